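# End-to-end orchestration: load inputs, blacklist-filter peaks, cluster
# promoter states, classify expression, call bivalent domains, test the
# DEG/BD overlap and per-cluster enrichment, compute the PI time course,
# and summarize qPCR occupancies. Deterministic given the config.

#' Default pipeline parameters
#' @return named list of tunable parameters with their defaults.
#' @export
pipeline_defaults <- function() {
  list(eps = 0.01, half_width = 1000, k_min = 2L, k_max = 10L, seed = 1L,
       nstart = 25L, fc_up = 2, fdr_max = 0.1, fpkm_min = 1,
       tss_upstream = 50, tss_downstream = 300,
       body_start_offset = 300, body_end_offset = 2000, min_body = 300,
       transform = "log_z", qpcr_convention = "site")
}

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file with the same shape)
#' with `inputs` (paths: `genes`, `marks` = named list of bedGraph paths
#' for the clustering marks, `input` bedGraph, `rnapii` = named list by
#' time point, `input_by_time` = named list by time point, `k4_peaks`,
#' `k27_peaks`, optional `blacklist`, `expression`, optional `ct`) and
#' optional `params` overriding [pipeline_defaults()]. Every referenced
#' path must exist.
#'
#' @param config list or path to a YAML file.
#' @return the validated config with defaults filled in.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$inputs))
  params <- utils::modifyList(pipeline_defaults(), config$params %||% list())
  paths <- c(config$inputs$genes, unlist(config$inputs$marks),
             config$inputs$input, unlist(config$inputs$rnapii),
             unlist(config$inputs$input_by_time),
             config$inputs$k4_peaks, config$inputs$k27_peaks,
             config$inputs$blacklist, config$inputs$expression,
             config$inputs$ct)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  stopifnot(params$eps > 0, params$half_width > 0, params$k_min >= 2,
            params$k_max >= params$k_min, params$fc_up > 1,
            params$fdr_max >= 0, params$fdr_max <= 1)
  config$params <- params
  config
}

#' Run the full analysis pipeline
#'
#' Stage order: signal quantification and promoter-state clustering,
#' expression classification, blacklist filtering and bivalent-domain
#' calling, DEG/BD intersection and overlap test, per-cluster enrichment
#' of DEGs and bdDEGs, pausing-index time course, and (if a Ct table is
#' provided) qPCR occupancy summaries. Writes one TSV per stage plus a
#' JSON run manifest recording the package version, parameters, seeds and
#' MD5 checksums of inputs and outputs. Rerunning with the same config
#' reproduces identical output files.
#'
#' @param config see [validate_pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the stage results and `manifest`.
#' @export
run_pipeline <- function(config, outdir) {
  config <- validate_pipeline_config(config)
  par <- config$params
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  inp <- config$inputs

  genes <- read_gene_models(inp$genes)
  mark_tracks <- lapply(inp$marks, read_bedgraph)
  input_track <- read_bedgraph(inp$input)
  expr <- read_expression(inp$expression)
  k4 <- read_peaks(inp$k4_peaks, dialect = "narrowPeak")
  k27 <- read_peaks(inp$k27_peaks, dialect = "narrowPeak")

  ns <- check_chrom_namespace(genes = genes, input = input_track,
                              k4_peaks = k4, k27_peaks = k27)
  outputs <- character()
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv(df, p)
    outputs[[name]] <<- p
  }
  if (nrow(ns)) emit(ns, "chromosome_namespace_report.tsv")

  # promoter-state clustering
  mat <- build_promoter_matrix(mark_tracks, input_track, genes,
                               half_width = par$half_width, eps = par$eps,
                               transform = par$transform)
  clusters <- select_k_and_cluster(mat, k_range = par$k_min:par$k_max,
                                   seed = par$seed, nstart = par$nstart)
  emit(data.frame(gene_id = names(clusters$labels), cluster = clusters$labels),
       "clusters.tsv")
  emit(data.frame(k = as.integer(names(clusters$silhouette_by_k)),
                  mean_silhouette = clusters$silhouette_by_k),
       "silhouette.tsv")

  # expression classes
  classes <- classify_expression(expr, fc_up = par$fc_up, fdr_max = par$fdr_max,
                                 fpkm_min = par$fpkm_min)
  emit(classes, "expression_classes.tsv")
  degs <- classes$gene_id[classes$is_deg]

  # bivalent calling on blacklist-filtered peaks
  if (!is.null(inp$blacklist)) {
    bl <- read_peaks(inp$blacklist, dialect = "bed3")
    k4 <- filter_blacklist(k4, bl)
    k27 <- filter_blacklist(k27, bl)
  }
  calls <- call_bivalent(genes, k4, k27, half_width = par$half_width)
  emit(as.data.frame(calls), "bd_calls.tsv")

  # DEG/BD overlap
  venn <- intersect_with_set(calls, degs)
  # the expressed-gene universe anchors the independence expectation
  universe <- intersect(names(clusters$labels),
                        classes$gene_id[classes$is_expressed])
  ov <- overlap_test(n_universe = length(universe),
                     n_setA = sum(degs %in% universe),
                     n_setB = sum(calls$gene_id %in% universe),
                     n_overlap = sum(venn$bd_and_set %in% universe))
  emit(data.frame(n_universe = length(universe),
                  n_deg = sum(degs %in% universe),
                  n_bd = sum(calls$gene_id %in% universe),
                  n_overlap = sum(venn$bd_and_set %in% universe),
                  expected = ov$expected, chi2 = ov$chi2, p = ov$p),
       "deg_bd_overlap.tsv")

  # per-cluster enrichment of DEGs and bdDEGs
  deg_in_uni <- intersect(degs, names(clusters$labels))
  enr_deg <- cluster_enrichment(clusters, deg_in_uni)
  emit(enr_deg, "enrichment_deg.tsv")
  bddeg <- intersect(venn$bd_and_set, names(clusters$labels))
  enr_bddeg <- if (length(bddeg)) cluster_enrichment(clusters, bddeg) else NULL
  if (!is.null(enr_bddeg)) emit(enr_bddeg, "enrichment_bddeg.tsv")

  # pausing-index time course
  pi_tc <- NULL
  if (!is.null(inp$rnapii)) {
    tps <- names(inp$rnapii)
    recs <- lapply(tps, function(tp) {
      pausing_index(read_bedgraph(inp$rnapii[[tp]]),
                    read_bedgraph(inp$input_by_time[[tp]]), genes,
                    tss_upstream = par$tss_upstream,
                    tss_downstream = par$tss_downstream,
                    body_start_offset = par$body_start_offset,
                    body_end_offset = par$body_end_offset,
                    min_body = par$min_body, eps = par$eps)
    })
    names(recs) <- tps
    pi_tc <- suppressWarnings(pi_timecourse(recs))
    emit(pi_tc$table, "pi_timecourse.tsv")
  }

  # qPCR occupancy
  qpcr <- NULL
  if (!is.null(inp$ct)) {
    qpcr <- occupancy_table(read_ct_table(inp$ct),
                            convention = par$qpcr_convention)
    emit(qpcr$per_site, "qpcr_occupancy.tsv")
  }

  manifest <- list(
    package = "bivalomics",
    version = as.character(utils::packageVersion("bivalomics")),
    parameters = par,
    seed = par$seed,
    selected_k = clusters$K,
    input_md5 = as.list(tools::md5sum(sort(unname(c(
      inp$genes, unlist(inp$marks), inp$input, unlist(inp$rnapii),
      unlist(inp$input_by_time), inp$k4_peaks, inp$k27_peaks,
      inp$blacklist, inp$expression, inp$ct))))),
    output_md5 = as.list(tools::md5sum(unname(unlist(outputs)))))
  manifest_path <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(clusters = clusters, classes = classes, calls = calls,
                 venn = venn, overlap = ov, enrichment_deg = enr_deg,
                 enrichment_bddeg = enr_bddeg, pi_timecourse = pi_tc,
                 qpcr = qpcr, manifest = manifest, outputs = outputs))
}

#' Build a pipeline config pointing at a written fixture tree
#'
#' Convenience for running [run_pipeline()] on the output of
#' [write_fixture()]: clustering uses the hour-0 mark tracks (the
#' pre-stimulation state defines cluster identity) and the pausing stage
#' uses all four RNAPII/input time points.
#'
#' @param fixture_dir directory written by [write_fixture()].
#' @param params optional parameter overrides.
#' @return a config list for [run_pipeline()].
#' @export
fixture_pipeline_config <- function(fixture_dir, params = list()) {
  tr <- function(nm) file.path(fixture_dir, "tracks", paste0(nm, ".bedGraph"))
  tps <- c("0", "1", "4", "12")
  list(inputs = list(
    genes = file.path(fixture_dir, "genes.tsv"),
    marks = stats::setNames(
      lapply(SYNTH_MARKS, function(m) tr(paste0(m, "_0h"))), SYNTH_MARKS),
    input = tr("input_0h"),
    rnapii = stats::setNames(lapply(tps, function(t) tr(paste0("RNAPII_", t, "h"))), tps),
    input_by_time = stats::setNames(lapply(tps, function(t) tr(paste0("input_", t, "h"))), tps),
    k4_peaks = file.path(fixture_dir, "peaks", "H3K4me3_0h.narrowPeak"),
    k27_peaks = file.path(fixture_dir, "peaks", "H3K27me3_0h.narrowPeak"),
    blacklist = file.path(fixture_dir, "blacklist.bed"),
    expression = file.path(fixture_dir, "expression.tsv"),
    ct = file.path(fixture_dir, "ct.tsv")),
    params = params)
}
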