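# Deterministic synthetic-data generator: a toy genome with coverage
# tracks, peak sets, expression and Ct tables carrying the statistical
# structure the pipeline assumes, plus a ground-truth manifest.

#' Default promoter chromatin-state specification (six states)
#'
#' Mean log2 input-normalized promoter signal per mark for six planted
#' promoter states: empty chromatin, weak H3K27ac only, strong bivalent,
#' fully active, repressed, and weak bivalent. Means are configuration,
#' not hard-coded biology; the per-state standard deviation (0.25) puts
#' neighbouring states >= 5 standard deviations apart.
#'
#' @return data.frame with `cluster`, one `mu_<mark>` column per mark, `sd`.
#' @export
default_cluster_spec <- function() {
  data.frame(
    cluster = 1:6,
    mu_H3K4me2  = c(0, 0,   2,   2.5, 0,   1),
    mu_H3K4me3  = c(0, 0,   2.5, 3,   0,   1.5),
    mu_H3K27ac  = c(0, 1.5, 1,   2.5, 0,   0.3),
    mu_H3K27me3 = c(0, 0,   2.5, 0,   2.5, 2.5),
    sd = 0.25)
}

#' Synthetic-data configuration
#'
#' Defines the toy study: a 4-time-point (0/1/4/12 h) stimulation course
#' with coverage tracks for four histone marks, RNAPII and input, matched
#' peak sets, an expression table and a ChIP-qPCR Ct table. Defaults give
#' 500 genes on two 2.5-Mb chromosomes, 120 bivalent promoters drawn from
#' the two bivalent states, 90 DEGs with a 3-fold DEG enrichment in
#' bivalent promoters, and RNAPII pausing (median planted PI 8) with a
#' 4-fold pause release at 1 h in 30% of DEGs.
#'
#' @param seed integer seed; the whole bundle is a deterministic function
#'   of the config.
#' @param n_chromosomes,chrom_length toy genome shape.
#' @param n_genes,n_bd_genes,n_deg gene counts (BD genes and DEGs are
#'   subsets of the genes).
#' @param bd_deg_enrichment_fold target `P(DEG | BD) / P(DEG | not BD)`.
#' @param cluster_spec promoter-state means, see [default_cluster_spec()].
#' @param pause_spec list with `fraction_paused` (of all genes),
#'   `pi_median` (planted PI of paused genes at 0 h), `release_fold`
#'   (PI drop at 1 h for paused DEGs).
#' @param noise_sd bin-level relative noise of the input track.
#' @param frac_unexpressed fraction of genes with FPKM < 1 at all time
#'   points.
#' @param bin_width coverage emission bin width in bp (default 10).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 7L, n_chromosomes = 2L, chrom_length = 2.5e6,
                         n_genes = 500L, n_bd_genes = 120L, n_deg = 90L,
                         bd_deg_enrichment_fold = 3,
                         cluster_spec = default_cluster_spec(),
                         pause_spec = list(fraction_paused = 0.3, pi_median = 8,
                                           release_fold = 4),
                         noise_sd = 0.01, frac_unexpressed = 0.1,
                         bin_width = 10L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length, n_genes = as.integer(n_genes),
              n_bd_genes = as.integer(n_bd_genes), n_deg = as.integer(n_deg),
              bd_deg_enrichment_fold = bd_deg_enrichment_fold,
              cluster_spec = cluster_spec, pause_spec = pause_spec,
              noise_sd = noise_sd, frac_unexpressed = frac_unexpressed,
              bin_width = as.integer(bin_width))
  stopifnot(cfg$n_bd_genes <= cfg$n_genes, cfg$n_deg <= cfg$n_genes,
            cfg$bd_deg_enrichment_fold >= 1, all(cfg$cluster_spec$sd > 0),
            cfg$noise_sd >= 0)
  structure(cfg, class = "synth_config")
}

GENE_PITCH <- 10000L      # one gene slot per 10 kb
TIME_POINTS <- c("0", "1", "4", "12")
SYNTH_MARKS <- c("H3K4me2", "H3K4me3", "H3K27ac", "H3K27me3")

#' Generate a synthetic data bundle
#'
#' Plants, per gene: a promoter chromatin state (log-normal promoter
#' signal around the state mean), bivalent-domain status (both H3K4me3 and
#' H3K27me3 peaks at the promoter, lower planted expression), DEG status
#' sampled so that `P(DEG | BD)` is `bd_deg_enrichment_fold` times
#' `P(DEG | not BD)`, a temporal response class realized in the
#' fold-change/FDR columns (planted DEGs get FDR in [0, 0.1], non-DEGs in
#' [0.2, 1]), and an RNAPII pausing index realized in the coverage tracks
#' as a TSS pulse over a gene-body plateau, with paused DEGs released
#' `release_fold`-fold at 1 h. Input tracks are uniform at 1 with
#' block-level noise. Histone promoter states are held constant over the
#' course (the planted cluster identity is the pre-stimulation state).
#'
#' All randomness derives from `config$seed`: identical configs give
#' identical bundles.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_bundle`: `genes` (`gene_models`), `tracks`
#'   (named list: per mark and `RNAPII`/`input`, a named list of
#'   [coverage_track()]s by time point), `peaks` (named list with
#'   `H3K4me3`, `H3K27me3` `peak_set`s and `blacklist`), `expression`,
#'   `ct`, `manifest` (per-gene ground truth), `config`.
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cfg <- config
  bw <- cfg$bin_width
  n_slots_per_chrom <- floor(cfg$chrom_length / GENE_PITCH)
  if (cfg$n_genes > n_slots_per_chrom * cfg$n_chromosomes)
    stop("too many genes for the genome: at most ",
         n_slots_per_chrom * cfg$n_chromosomes, call. = FALSE)

  ## gene models: one gene per 10-kb slot, coordinates on the bin grid
  idx <- seq_len(cfg$n_genes) - 1L
  chrom_i <- (idx %% cfg$n_chromosomes) + 1L
  slot_i <- idx %/% cfg$n_chromosomes
  slot0 <- slot_i * GENE_PITCH
  len <- sample(seq(2000L, 6000L, by = bw), cfg$n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  start <- ifelse(strand == "+", slot0 + 1500L, slot0 + 8500L - len)
  end <- start + len
  genes <- gene_models(data.frame(
    gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
    chrom = paste0("chrS", chrom_i),
    start = start, end = end, strand = strand))

  ## promoter states
  spec <- cfg$cluster_spec
  K <- nrow(spec)
  sizes <- rep(floor(cfg$n_genes / K), K)
  sizes[seq_len(cfg$n_genes - sum(sizes))] <- sizes[seq_len(cfg$n_genes - sum(sizes))] + 1L
  perm <- sample.int(cfg$n_genes)
  cluster <- integer(cfg$n_genes)
  cluster[perm] <- rep(seq_len(K), times = sizes)
  mu <- as.matrix(spec[paste0("mu_", SYNTH_MARKS)])
  l2r <- mu[cluster, , drop = FALSE] +
    matrix(stats::rnorm(cfg$n_genes * length(SYNTH_MARKS), 0, spec$sd[cluster]),
           ncol = length(SYNTH_MARKS))
  colnames(l2r) <- SYNTH_MARKS
  ratio <- 2^l2r

  ## bivalent promoters: drawn from the two bivalent-like states (3 and 6)
  bd_pool <- which(cluster %in% c(3L, 6L))
  if (length(bd_pool) < cfg$n_bd_genes)
    stop("bivalent states hold only ", length(bd_pool), " genes; lower n_bd_genes",
         call. = FALSE)
  is_bd <- logical(cfg$n_genes)
  is_bd[sample(bd_pool, cfg$n_bd_genes)] <- TRUE

  ## DEG membership with planted BD enrichment
  p_nonbd <- cfg$n_deg / (cfg$bd_deg_enrichment_fold * cfg$n_bd_genes +
                            (cfg$n_genes - cfg$n_bd_genes))
  p_bd <- cfg$bd_deg_enrichment_fold * p_nonbd
  if (p_bd > 1)
    stop("infeasible enrichment: implied P(DEG | BD) = ", round(p_bd, 3), " > 1",
         call. = FALSE)
  n_deg_bd <- round(p_bd * cfg$n_bd_genes)
  n_deg_nonbd <- cfg$n_deg - n_deg_bd
  is_deg <- logical(cfg$n_genes)
  is_deg[sample(which(is_bd), n_deg_bd)] <- TRUE
  is_deg[sample(which(!is_bd), n_deg_nonbd)] <- TRUE

  ## temporal classes for DEGs: ~45% early-up, 30% late-up, 25% down
  deg_idx <- which(is_deg)
  n_early <- round(0.45 * length(deg_idx))
  n_late <- round(0.30 * length(deg_idx))
  shuffled <- sample(deg_idx)
  temporal <- rep("none", cfg$n_genes)
  temporal[shuffled[seq_len(n_early)]] <- "early_up"
  temporal[shuffled[n_early + seq_len(n_late)]] <- "late_up"
  temporal[shuffled[-(seq_len(n_early + n_late))]] <- "down"

  ## expression table
  expr <- .synth_expression(cfg, genes$gene_id, is_bd, is_deg, temporal)

  ## pausing: stratified so that exactly 30% of DEGs are paused (these are
  ## the pause-release genes) and the overall paused fraction is met
  n_paused <- round(cfg$pause_spec$fraction_paused * cfg$n_genes)
  n_paused_deg <- min(round(cfg$pause_spec$fraction_paused * length(deg_idx)),
                      n_paused)
  is_paused <- logical(cfg$n_genes)
  is_paused[sample(deg_idx, n_paused_deg)] <- TRUE
  is_paused[sample(which(!is_deg), n_paused - n_paused_deg)] <- TRUE
  is_release <- is_paused & is_deg
  pi0 <- ifelse(is_paused,
                stats::rlnorm(cfg$n_genes, log(cfg$pause_spec$pi_median), 0.4),
                stats::rlnorm(cfg$n_genes, log(2), 0.3))
  jit <- function() 2^stats::rnorm(cfg$n_genes, 0, 0.02)
  rf <- cfg$pause_spec$release_fold
  pi_t <- cbind(`0` = pi0,
                `1` = ifelse(is_release, pi0 / rf, pi0 * jit()),
                `4` = ifelse(is_release, pi0 / (rf / 2), pi0 * jit()),
                `12` = ifelse(is_release, pi0, pi0 * jit()))

  ## coverage tracks
  chroms <- paste0("chrS", seq_len(cfg$n_chromosomes))
  tracks <- list()
  for (mk in SYNTH_MARKS) {
    tr <- .synth_mark_track(genes, ratio[, mk], chroms, cfg$chrom_length, bw,
                            label = mk)
    tracks[[mk]] <- stats::setNames(rep(list(tr), length(TIME_POINTS)), TIME_POINTS)
    for (tp in TIME_POINTS) tracks[[mk]][[tp]]$label <- paste0(mk, "_", tp, "h")
  }
  tracks$RNAPII <- stats::setNames(lapply(TIME_POINTS, function(tp) {
    b <- rep(0.5, cfg$n_genes)
    if (any(is_release)) {
      scale_t <- c(`0` = 1, `1` = rf, `4` = rf / 2, `12` = 1)[[tp]]
      b[is_release] <- 0.5 * scale_t
    }
    .synth_rnapii_track(genes, pi_t[, tp], b, chroms, cfg$chrom_length, bw,
                        label = paste0("RNAPII_", tp, "h"))
  }), TIME_POINTS)
  tracks$input <- stats::setNames(lapply(TIME_POINTS, function(tp) {
    .synth_input_track(chroms, cfg$chrom_length, cfg$noise_sd,
                       label = paste0("input_", tp, "h"))
  }), TIME_POINTS)

  ## peak sets: both marks at BD promoters; K4-only at active states,
  ## K27-only at the repressed state; decoy peaks inside the blacklist
  has_k4 <- is_bd | cluster %in% c(3L, 4L, 6L)
  has_k27 <- is_bd | cluster == 5L
  k4 <- .promoter_peaks(genes, has_k4, half = 400L, prefix = "k4")
  k27 <- .promoter_peaks(genes, has_k27, half = 600L, prefix = "k27")
  bl_n <- 5L
  bl <- data.frame(chrom = chroms[1L],
                   start = (seq_len(bl_n) - 1L) * GENE_PITCH + 9600,
                   end = (seq_len(bl_n) - 1L) * GENE_PITCH + 9900)
  decoy <- function(prefix) data.frame(
    chrom = bl$chrom, start = bl$start + 50, end = bl$end - 50,
    name = sprintf("%s_decoy_%d", prefix, seq_len(bl_n)),
    score = 1000, strand = ".", signal = 99, pvalue = 99, qvalue = 99,
    summit = 100, stringsAsFactors = FALSE)
  k4 <- peak_set(rbind(k4, decoy("k4")), "H3K4me3_0h")
  k27 <- peak_set(rbind(k27, decoy("k27")), "H3K27me3_0h")

  ## ChIP-qPCR Ct table: 8 test sites + 1 control, 4 replicates
  n_sites <- 8L
  planted_occ <- 2^stats::runif(n_sites, -1, 3)
  ct <- .synth_ct(planted_occ)

  manifest <- data.frame(gene_id = genes$gene_id, cluster = cluster,
                         is_bd = is_bd, is_deg = is_deg,
                         temporal_class = temporal,
                         is_paused = is_paused, is_release = is_release,
                         pi_0h = pi_t[, "0"], pi_1h = pi_t[, "1"],
                         pi_4h = pi_t[, "4"], pi_12h = pi_t[, "12"],
                         stringsAsFactors = FALSE)
  structure(list(genes = genes, tracks = tracks,
                 peaks = list(H3K4me3 = k4, H3K27me3 = k27,
                              blacklist = peak_set(bl, "blacklist")),
                 expression = expr, ct = ct,
                 qpcr_truth = data.frame(site_id = sprintf("site_%d", seq_len(n_sites)),
                                         planted_occupancy = planted_occ),
                 manifest = manifest, config = cfg),
            class = "synth_bundle")
}

# expression table with planted DEG structure; boundary DEG planted at
# exactly FC = 2 / FDR = 0.1 on the first early-up gene
.synth_expression <- function(cfg, gene_ids, is_bd, is_deg, temporal) {
  n <- length(gene_ids)
  base <- ifelse(is_bd, pmax(stats::rlnorm(n, log(4), 0.5), 1.05),
                 pmax(stats::rlnorm(n, log(20), 0.5), 1.05))
  unexpr_pool <- which(!is_deg & !is_bd)
  n_unexpr <- min(round(cfg$frac_unexpressed * n), length(unexpr_pool))
  unexpr <- sample(unexpr_pool, n_unexpr)
  base[unexpr] <- stats::runif(n_unexpr, 0.01, 0.9)
  fc <- matrix(stats::runif(n * 3L, 0.75, 1.35), ncol = 3L,
               dimnames = list(NULL, c("1v0", "4v0", "12v0")))
  fdr <- matrix(stats::runif(n * 3L, 0.2, 1), ncol = 3L,
                dimnames = list(NULL, c("1v0", "4v0", "12v0")))
  sig_fc_up <- function(k) stats::runif(k, 2.2, 8)
  sig_fc_down <- function(k) stats::runif(k, 0.15, 0.5)
  sig_fdr <- function(k) stats::runif(k, 0, 0.1)
  early <- which(temporal == "early_up")
  late <- which(temporal == "late_up")
  down <- which(temporal == "down")
  fc[early, "1v0"] <- sig_fc_up(length(early))
  fdr[early, "1v0"] <- sig_fdr(length(early))
  also4 <- early[stats::runif(length(early)) < 0.5]
  fc[also4, "4v0"] <- sig_fc_up(length(also4))
  fdr[also4, "4v0"] <- sig_fdr(length(also4))
  late_comp <- sample(c("4v0", "12v0"), length(late), replace = TRUE)
  for (j in c("4v0", "12v0")) {
    sel <- late[late_comp == j]
    fc[sel, j] <- sig_fc_up(length(sel))
    fdr[sel, j] <- sig_fdr(length(sel))
  }
  down_comp <- sample(c("1v0", "4v0", "12v0"), length(down), replace = TRUE)
  for (j in c("1v0", "4v0", "12v0")) {
    sel <- down[down_comp == j]
    fc[sel, j] <- sig_fc_down(length(sel))
    fdr[sel, j] <- sig_fdr(length(sel))
  }
  if (length(early)) { fc[early[1L], "1v0"] <- 2.0; fdr[early[1L], "1v0"] <- 0.1 }
  if (length(down)) {
    j <- down_comp[1L]
    fc[down[1L], j] <- 0.5; fdr[down[1L], j] <- 0.1
  }
  fpkm0 <- base
  mk_fpkm <- function(comp) {
    out <- base * fc[, comp] * 2^stats::rnorm(n, 0, 0.05)
    # keep the expressed/unexpressed planting intact at every time point
    ifelse(base < 1, pmin(out, 0.95), pmax(out, 1.0))
  }
  data.frame(gene_id = gene_ids,
             fpkm_0h = fpkm0, fpkm_1h = mk_fpkm("1v0"),
             fpkm_4h = mk_fpkm("4v0"), fpkm_12h = mk_fpkm("12v0"),
             fc_1v0 = fc[, "1v0"], fc_4v0 = fc[, "4v0"], fc_12v0 = fc[, "12v0"],
             fdr_1v0 = fdr[, "1v0"], fdr_4v0 = fdr[, "4v0"], fdr_12v0 = fdr[, "12v0"],
             stringsAsFactors = FALSE)
}

# histone mark track: background 1.0, promoter windows elevated to the
# planted input-normalized ratio
.synth_mark_track <- function(genes, ratio, chroms, chrom_length, bw, label) {
  vals <- lapply(chroms, function(ch) rep(1.0, ceiling(chrom_length / bw)))
  names(vals) <- chroms
  g <- as.data.frame(genes)
  for (i in seq_len(nrow(g))) {
    b0 <- (g$tss[i] - 1000L) %/% bw + 1L
    b1 <- (g$tss[i] + 1000L) %/% bw
    vals[[g$chrom[i]]][b0:b1] <- ratio[i]
  }
  .vals_to_track(vals, bw, label)
}

# RNAPII track: background 0.2, gene-body plateau, TSS pulse sized so the
# measured PI (with input ~1 and eps = 0.01) equals the planted PI
.synth_rnapii_track <- function(genes, pi_target, body_value, chroms,
                                chrom_length, bw, label, eps = 0.01) {
  vals <- lapply(chroms, function(ch) rep(0.2, ceiling(chrom_length / bw)))
  names(vals) <- chroms
  g <- as.data.frame(genes)
  for (i in seq_len(nrow(g))) {
    ch <- g$chrom[i]
    if (g$strand[i] == "+") {
      body <- c(g$tss[i] + 300L, g$tes[i] + 2000L)
      tssw <- c(g$tss[i] - 50L, g$tss[i] + 300L)
    } else {
      body <- c(g$tes[i] - 2000L, g$tss[i] - 300L)
      tssw <- c(g$tss[i] - 300L, g$tss[i] + 50L)
    }
    s <- pi_target[i] * (body_value[i] + eps) - eps
    vals[[ch]][(body[1L] %/% bw + 1L):(body[2L] %/% bw)] <- body_value[i]
    vals[[ch]][(tssw[1L] %/% bw + 1L):(tssw[2L] %/% bw)] <- s
  }
  .vals_to_track(vals, bw, label)
}

# input track: uniform 1.0 with block-level (1 kb) gaussian noise
.synth_input_track <- function(chroms, chrom_length, noise_sd, label,
                               block = 1000L) {
  vals <- lapply(chroms, function(ch) {
    nb <- ceiling(chrom_length / block)
    pmax(1 + stats::rnorm(nb, 0, noise_sd), 0.1)
  })
  names(vals) <- chroms
  .vals_to_track(vals, block, label)
}

# run-length-compress per-bin value vectors into a coverage_track
.vals_to_track <- function(vals, bw, label) {
  bins <- do.call(rbind, lapply(names(vals), function(ch) {
    r <- rle(vals[[ch]])
    e <- cumsum(r$lengths) * bw
    s <- e - r$lengths * bw
    data.frame(chrom = ch, start = s, end = e, value = r$values,
               stringsAsFactors = FALSE)
  }))
  coverage_track(bins, label)
}

# narrowPeak-shaped promoter peaks for the selected genes
.promoter_peaks <- function(genes, sel, half, prefix) {
  g <- as.data.frame(genes)[sel, , drop = FALSE]
  data.frame(chrom = g$chrom, start = g$tss - half, end = g$tss + half,
             name = sprintf("%s_%s", prefix, g$gene_id),
             score = round(stats::runif(nrow(g), 50, 500)),
             strand = ".", signal = round(stats::runif(nrow(g), 5, 50), 2),
             pvalue = round(stats::runif(nrow(g), 5, 100), 2),
             qvalue = round(stats::runif(nrow(g), 2, 50), 2),
             summit = half, stringsAsFactors = FALSE)
}

# Ct table realizing the planted occupancies under the site convention
# (dCt_test = dCt_ctrl + log2(occupancy)); control site dCt = 5 cycles
.synth_ct <- function(planted_occ, n_rep = 4L) {
  n_sites <- length(planted_occ)
  rows <- list()
  for (r in seq_len(n_rep)) {
    ci <- stats::runif(1, 19, 21)
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = "ctrl_neg", role = "control", replicate = r,
      ct_chip = ci + 5 + stats::rnorm(1, 0, 0.05), ct_input = ci)
    for (s in seq_len(n_sites)) {
      ti <- stats::runif(1, 19, 21)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sprintf("site_%d", s), role = "test", replicate = r,
        ct_chip = ti + 5 + log2(planted_occ[s]) + stats::rnorm(1, 0, 0.05),
        ct_input = ti)
    }
  }
  do.call(rbind, rows)
}

#' Write a synthetic bundle as a fixture file tree
#'
#' Emits files valid for the package readers: `genes.tsv`,
#' `tracks/<label>.bedGraph`, `peaks/*.narrowPeak`, `blacklist.bed`,
#' `expression.tsv`, `ct.tsv`, `manifest.tsv` and `manifest.json`.
#' Byte-identical across runs with the same config.
#'
#' @param bundle a `synth_bundle` from [synth_generate()].
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(file.path(outdir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)
  paths <- c(genes = file.path(outdir, "genes.tsv"))
  write_gene_models(bundle$genes, paths[["genes"]])
  for (nm in names(bundle$tracks)) {
    for (tp in names(bundle$tracks[[nm]])) {
      p <- file.path(outdir, "tracks", sprintf("%s_%sh.bedGraph", nm, tp))
      write_bedgraph(bundle$tracks[[nm]][[tp]], p)
      paths[[sprintf("track_%s_%sh", nm, tp)]] <- p
    }
  }
  for (nm in c("H3K4me3", "H3K27me3")) {
    p <- file.path(outdir, "peaks", paste0(nm, "_0h.narrowPeak"))
    write_peaks(bundle$peaks[[nm]], p, dialect = "narrowPeak")
    paths[[paste0("peaks_", nm)]] <- p
  }
  paths[["blacklist"]] <- file.path(outdir, "blacklist.bed")
  write_peaks(bundle$peaks$blacklist, paths[["blacklist"]], dialect = "bed3")
  paths[["expression"]] <- file.path(outdir, "expression.tsv")
  write_tsv(bundle$expression, paths[["expression"]])
  paths[["ct"]] <- file.path(outdir, "ct.tsv")
  write_tsv(bundle$ct, paths[["ct"]])
  paths[["manifest"]] <- file.path(outdir, "manifest.tsv")
  write_tsv(bundle$manifest, paths[["manifest"]])
  paths[["manifest_json"]] <- file.path(outdir, "manifest.json")
  cfg <- unclass(bundle$config)
  cfg$cluster_spec <- NULL
  jsonlite::write_json(
    list(config = cfg,
         cluster_spec = bundle$config$cluster_spec,
         counts = list(n_genes = nrow(bundle$genes),
                       n_bd = sum(bundle$manifest$is_bd),
                       n_deg = sum(bundle$manifest$is_deg),
                       n_release = sum(bundle$manifest$is_release))),
    paths[["manifest_json"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
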