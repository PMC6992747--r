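# All coordinates in this package are 0-based half-open [start, end),
# the BED convention. Chromosome names are matched as exact strings.

#' Validate a table of genomic intervals
#'
#' Checks the package-wide interval invariants: non-empty chromosome name,
#' `start >= 0`, `end > start`. Coordinates are 0-based half-open.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `df`, invisibly, if valid; otherwise an error is thrown.
#' @keywords internal
validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop(what, ": empty chromosome name", call. = FALSE)
  if (any(df$start < 0))
    stop(what, ": negative start coordinate", call. = FALSE)
  if (any(df$end <= df$start))
    stop(what, ": end <= start (coordinates are 0-based half-open)", call. = FALSE)
  invisible(df)
}

#' Construct a coverage track
#'
#' A coverage track is a set of non-overlapping, per-chromosome sorted
#' `(start, end, value)` bins with bedGraph semantics: positions not covered
#' by any bin have implicit value 0. Bins may have any width.
#'
#' @param bins data.frame with columns `chrom`, `start`, `end`, `value`.
#'   Out-of-order bins are sorted; overlapping bins are an error.
#' @param label track label (mark/antibody plus time point).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(bins, label = "track") {
  stopifnot(is.data.frame(bins),
            all(c("chrom", "start", "end", "value") %in% names(bins)))
  bins <- bins[, c("chrom", "start", "end", "value")]
  bins$chrom <- as.character(bins$chrom)
  validate_intervals(bins, what = sprintf("coverage_track '%s'", label))
  if (any(is.na(bins$value)) || any(bins$value < 0))
    stop("coverage_track '", label, "': values must be non-negative", call. = FALSE)
  o <- order(bins$chrom, bins$start)
  bins <- bins[o, , drop = FALSE]
  same <- bins$chrom[-1L] == bins$chrom[-nrow(bins)]
  if (nrow(bins) > 1L && any(same & bins$start[-1L] < bins$end[-nrow(bins)]))
    stop("coverage_track '", label, "': overlapping bins", call. = FALSE)
  rownames(bins) <- NULL
  structure(list(bins = bins, label = label), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track '%s'> %d bins on %d chromosome(s)\n",
              x$label, nrow(x$bins), length(unique(x$bins$chrom))))
  invisible(x)
}

#' Read a bedGraph file into a coverage track
#'
#' @param path path to a 4-column whitespace-separated bedGraph file
#'   (chrom, start, end, value); `track`/`#` header lines are skipped.
#' @param label track label; defaults to the file name.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ln <- readLines(path)
  keep <- !grepl("^(track|#|browser)", ln) & nzchar(trimws(ln))
  if (!any(keep))
    return(coverage_track(data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), value = numeric()), label))
  fields <- strsplit(trimws(ln[keep]), "[ \t]+")
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    stop("malformed bedGraph line ", which(keep)[bad[1L]], " in ", path,
         " (expected 4 columns)", call. = FALSE)
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  value <- suppressWarnings(as.numeric(m[, 4L]))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad))
    stop("malformed bedGraph line ", which(keep)[bad[1L]], " in ", path, call. = FALSE)
  if (any(value < 0))
    stop("negative coverage value at line ", which(keep)[which(value < 0)[1L]],
         " in ", path, call. = FALSE)
  coverage_track(data.frame(chrom = m[, 1L], start = start, end = end,
                            value = value, stringsAsFactors = FALSE), label)
}

#' Write a coverage track as bedGraph
#'
#' @param track a [coverage_track()].
#' @param path output path. Tab-separated, newline-terminated, no header.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  b <- track$bins
  writeLines(sprintf("%s\t%d\t%d\t%s", b$chrom, as.integer(b$start),
                     as.integer(b$end), fmt_num(b$value)), path)
  invisible(path)
}

# fixed numeric formatting so generated fixtures are byte-identical per seed
fmt_num <- function(x) {
  out <- sprintf("%.8g", x)
  sub("\\.?0+$", "", out)
}

#' Read a peak file (BED3, BED6 or narrowPeak)
#'
#' @param path input path.
#' @param dialect one of `"bed3"`, `"bed6"`, `"narrowPeak"`. Column count
#'   must match (3, 6, 10). narrowPeak summits are parsed but unused
#'   downstream.
#' @param label peak-set label; defaults to the file name.
#' @return A `peak_set`: data.frame with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand` (and `signal`, `pvalue`, `qvalue`, `summit`
#'   for narrowPeak), with attribute `label`.
#' @export
read_peaks <- function(path, dialect = c("bed3", "bed6", "narrowPeak"),
                       label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ncol_want <- c(bed3 = 3L, bed6 = 6L, narrowPeak = 10L)[[dialect]]
  df <- tryCatch(
    as.data.frame(data.table::fread(path, header = FALSE, sep = "\t")),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(df) && ncol(df) != ncol_want)
    stop(path, ": expected ", ncol_want, " columns for dialect '", dialect,
         "', found ", ncol(df), call. = FALSE)
  if (!nrow(df)) df <- as.data.frame(matrix(nrow = 0, ncol = ncol_want))
  out <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.numeric(df[[2L]]),
                    end = as.numeric(df[[3L]]),
                    stringsAsFactors = FALSE)
  out$name <- if (ncol_want >= 6L) as.character(df[[4L]]) else sprintf("peak_%d", seq_len(nrow(out)))
  out$score <- if (ncol_want >= 6L) as.numeric(df[[5L]]) else NA_real_
  out$strand <- if (ncol_want >= 6L) as.character(df[[6L]]) else "."
  if (dialect == "narrowPeak") {
    out$signal <- as.numeric(df[[7L]])
    out$pvalue <- as.numeric(df[[8L]])
    out$qvalue <- as.numeric(df[[9L]])
    out$summit <- as.numeric(df[[10L]])
  }
  validate_intervals(out, what = sprintf("peak set '%s'", label))
  peak_set(out, label)
}

#' Construct a peak set
#'
#' @param df data.frame with at least `chrom`, `start`, `end`.
#' @param label non-empty label.
#' @return data.frame of class `peak_set`.
#' @export
peak_set <- function(df, label = "peaks") {
  if (!nzchar(label)) stop("peak set label must be non-empty", call. = FALSE)
  validate_intervals(df, what = sprintf("peak set '%s'", label))
  if (is.null(df$strand)) df$strand <- "."
  if (is.null(df$name)) df$name <- sprintf("peak_%d", seq_len(nrow(df)))
  if (is.null(df$score)) df$score <- NA_real_
  rownames(df) <- NULL
  structure(df, label = label, class = c("peak_set", "data.frame"))
}

#' Write a peak set
#'
#' @param peaks a `peak_set`.
#' @param path output path.
#' @param dialect output dialect; `"narrowPeak"` requires the narrowPeak
#'   columns to be present.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, dialect = c("bed3", "bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  p <- as.data.frame(peaks)
  lines <- switch(dialect,
    bed3 = sprintf("%s\t%d\t%d", p$chrom, as.integer(p$start), as.integer(p$end)),
    bed6 = sprintf("%s\t%d\t%d\t%s\t%s\t%s", p$chrom, as.integer(p$start),
                   as.integer(p$end), p$name, fmt_num(p$score), p$strand),
    narrowPeak = sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%d",
                         p$chrom, as.integer(p$start), as.integer(p$end), p$name,
                         fmt_num(p$score), p$strand, fmt_num(p$signal),
                         fmt_num(p$pvalue), fmt_num(p$qvalue), as.integer(p$summit)))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models
#'
#' Reads a tab-separated gene-model table with header columns `gene_id`,
#' `chrom`, `start`, `end`, `strand`. Coordinates are 0-based half-open.
#' The TSS and TES are derived from strand: for `+` genes TSS = start and
#' TES = end; for `-` genes TSS = end and TES = start.
#'
#' @param path input TSV path.
#' @return data.frame of class `gene_models` with added `tss`, `tes`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop(path, ": missing columns ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  gene_models(df[, need])
}

#' Construct gene models from a data.frame
#'
#' @param df data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @return data.frame of class `gene_models` with `tss` and `tes` columns.
#' @export
gene_models <- function(df) {
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  df$strand <- as.character(df$strand)
  validate_intervals(df, what = "gene model")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)])[1:3], collapse = ", "),
         call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'", call. = FALSE)
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df$tes <- ifelse(df$strand == "+", df$end, df$start)
  rownames(df) <- NULL
  structure(df, class = c("gene_models", "data.frame"))
}

#' Write gene models as TSV
#'
#' @param genes a `gene_models` data.frame.
#' @param path output path; header row, tab-separated.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  write_tsv(as.data.frame(genes)[, c("gene_id", "chrom", "start", "end", "strand")],
            path)
}

#' Read a per-gene expression table
#'
#' Expected header columns: `gene_id`, `fpkm_0h`, `fpkm_1h`, `fpkm_4h`,
#' `fpkm_12h`, `fc_1v0`, `fc_4v0`, `fc_12v0`, `fdr_1v0`, `fdr_4v0`,
#' `fdr_12v0`. Fold changes are linear ratios versus hour 0 and must be
#' positive; FDR values lie in `[0, 1]`.
#'
#' @param path input TSV path.
#' @return data.frame with the eleven required columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  need <- c("gene_id", paste0("fpkm_", c(0, 1, 4, 12), "h"),
            paste0("fc_", c(1, 4, 12), "v0"), paste0("fdr_", c(1, 4, 12), "v0"))
  if (!all(need %in% names(df)))
    stop(path, ": missing columns ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  validate_expression(df[, need])
}

validate_expression <- function(df) {
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in expression table", call. = FALSE)
  fpkm <- as.matrix(df[paste0("fpkm_", c(0, 1, 4, 12), "h")])
  if (any(is.na(fpkm)) || any(fpkm < 0)) stop("FPKM must be >= 0", call. = FALSE)
  fc <- as.matrix(df[paste0("fc_", c(1, 4, 12), "v0")])
  if (any(is.na(fc)) || any(fc <= 0)) stop("fold change must be > 0", call. = FALSE)
  fdr <- as.matrix(df[paste0("fdr_", c(1, 4, 12), "v0")])
  if (any(is.na(fdr)) || any(fdr < 0) || any(fdr > 1)) stop("FDR must be in [0, 1]", call. = FALSE)
  df
}

#' Read a ChIP-qPCR Ct table
#'
#' Expected header columns: `site_id`, `role` (`test` or `control`),
#' `replicate`, `ct_chip`, `ct_input`. Ct values must lie in (0, 45);
#' each (site, replicate) pair must be unique.
#'
#' @param path input TSV path.
#' @return validated data.frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  need <- c("site_id", "role", "replicate", "ct_chip", "ct_input")
  if (!all(need %in% names(df)))
    stop(path, ": missing columns ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  validate_ct_table(df[, need])
}

validate_ct_table <- function(df) {
  df$site_id <- as.character(df$site_id)
  df$role <- as.character(df$role)
  if (!all(df$role %in% c("test", "control")))
    stop("role must be 'test' or 'control'", call. = FALSE)
  ct <- c(df$ct_chip, df$ct_input)
  if (any(is.na(ct)) || any(ct <= 0) || any(ct >= 45))
    stop("Ct values must lie in (0, 45)", call. = FALSE)
  if (anyDuplicated(df[, c("site_id", "replicate")]))
    stop("duplicate (site_id, replicate) pair", call. = FALSE)
  df
}

#' Write a data.frame as a tab-separated table with header
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1L))
  for (j in which(num)) {
    intish <- all(is.na(df[[j]]) | df[[j]] == round(df[[j]]))
    df[[j]] <- if (intish) as.character(as.integer(round(df[[j]]))) else fmt_num(df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Report chromosome-namespace mismatches between inputs
#'
#' Chromosome names are matched as exact strings throughout the package;
#' this validation pass lists chromosomes present in one input but not
#' another, the classic silent failure mode of mixed references.
#'
#' @param ... named inputs: `coverage_track`, `peak_set`, or `gene_models`.
#' @return data.frame with one row per (input, chromosome) missing from at
#'   least one other input; zero rows when namespaces agree.
#' @export
check_chrom_namespace <- function(...) {
  inputs <- list(...)
  stopifnot(length(inputs) >= 2L, !is.null(names(inputs)), all(nzchar(names(inputs))))
  chroms <- lapply(inputs, function(x) {
    if (inherits(x, "coverage_track")) unique(x$bins$chrom)
    else unique(as.data.frame(x)$chrom)
  })
  all_chroms <- sort(unique(unlist(chroms)))
  rows <- do.call(rbind, lapply(names(chroms), function(nm) {
    miss <- setdiff(all_chroms, chroms[[nm]])
    if (!length(miss)) return(NULL)
    data.frame(input = nm, missing_chrom = miss, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame(input = character(), missing_chrom = character())
  rows
}

# Convert 0-based half-open intervals to GRanges (1-based closed) for
# overlap machinery. The base set is identical: [s, e) == [s+1, e].
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (!is.null(df$strand)) ifelse(df$strand %in% c("+", "-"), df$strand, "*") else "*")
}
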