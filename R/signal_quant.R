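# Interval signal quantification: totals/densities over strand-resolved
# windows, input normalization, blacklist filtering, profile matrices.

#' Window specification anchored at TSS, TES or the gene body
#'
#' `upstream` counts base pairs against the direction of transcription and
#' `downstream` with it, so a TSS window of (-50, +300) is
#' `window_spec("TSS", 50, 300)`. For the `genebody` anchor the window runs
#' from `upstream` bp before the TSS to `downstream` bp past the TES.
#'
#' @param anchor `"TSS"`, `"TES"` or `"genebody"`.
#' @param upstream,downstream non-negative extents in bp (negative values
#'   shrink the window past the anchor and are allowed, e.g. a body window
#'   starting downstream of the TSS uses `upstream = -300`).
#' @return object of class `window_spec`.
#' @export
window_spec <- function(anchor = c("TSS", "TES", "genebody"),
                        upstream = 1000, downstream = 1000) {
  anchor <- match.arg(anchor)
  structure(list(anchor = anchor, upstream = upstream, downstream = downstream),
            class = "window_spec")
}

#' Resolve a window specification on genes, strand-aware
#'
#' "Upstream" always means opposite to the direction of transcription: for
#' a minus-strand gene with TSS at 1000, a TSS window of (-50, +300)
#' resolves to `[700, 1050)`. Windows are clipped at position 0; a window
#' entirely off-chromosome is an error.
#'
#' @param genes a `gene_models` data.frame (one or more rows).
#' @param spec a [window_spec()].
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
resolve_window <- function(genes, spec) {
  stopifnot(inherits(spec, "window_spec"))
  g <- as.data.frame(genes)
  plus <- g$strand == "+"
  a_start <- switch(spec$anchor, TSS = g$tss, TES = g$tes, genebody = g$tss)
  a_end <- switch(spec$anchor, TSS = g$tss, TES = g$tes, genebody = g$tes)
  start <- ifelse(plus, a_start - spec$upstream, a_end - spec$downstream)
  end <- ifelse(plus, a_end + spec$downstream, a_start + spec$upstream)
  if (any(end <= start))
    stop("window length must be > 0 after strand-aware resolution", call. = FALSE)
  end_clip <- end
  start_clip <- pmax(start, 0)
  if (any(end_clip <= 0))
    stop("window entirely off-chromosome for gene(s): ",
         paste(g$gene_id[end_clip <= 0], collapse = ", "), call. = FALSE)
  data.frame(gene_id = g$gene_id, chrom = g$chrom, start = start_clip,
             end = end_clip, strand = g$strand, stringsAsFactors = FALSE)
}

#' Signal total and density of a coverage track over intervals
#'
#' The total is the sum over bins of `value x overlap-length` with the
#' query interval (signal-bp); the density is `total / interval length`
#' (signal per bp). Positions without coverage contribute zero.
#'
#' @param track a [coverage_track()].
#' @param intervals data.frame with `chrom`, `start`, `end` (one or more
#'   rows), 0-based half-open.
#' @return data.frame with columns `total`, `length`, `density`, one row
#'   per interval, in input order.
#' @export
interval_signal <- function(track, intervals) {
  stopifnot(inherits(track, "coverage_track"))
  iv <- as.data.frame(intervals)
  validate_intervals(iv, what = "query interval")
  n <- nrow(iv)
  total <- numeric(n)
  b <- track$bins
  for (ch in unique(iv$chrom)) {
    qi <- which(iv$chrom == ch)
    bi <- b[b$chrom == ch, , drop = FALSE]
    if (!nrow(bi)) next
    total[qi] <- .signal_totals(bi$start, bi$end, bi$value, iv$start[qi], iv$end[qi])
  }
  len <- iv$end - iv$start
  data.frame(total = total, length = len, density = total / len)
}

# Fast totals on one chromosome. Bins are sorted and non-overlapping, so
# at most the first and last overlapping bin are partially covered.
.signal_totals <- function(bs, be, bv, qs, qe) {
  w <- be - bs
  cum <- c(0, cumsum(bv * w))
  i1 <- findInterval(qs, be) + 1L          # first bin with end > qs
  i2 <- findInterval(qe - 0.5, bs)         # last bin with start < qe
  out <- numeric(length(qs))
  hit <- i1 <= i2
  if (!any(hit)) return(out)
  i1h <- i1[hit]; i2h <- i2[hit]
  full <- cum[i2h + 1L] - cum[i1h]
  left_cut <- bv[i1h] * pmax(0, qs[hit] - bs[i1h])
  right_cut <- bv[i2h] * pmax(0, be[i2h] - qe[hit])
  out[hit] <- full - left_cut - right_cut
  out
}

#' Normalize ChIP signal density to input
#'
#' Forms the input-normalized ratio
#' `(chip density + eps) / (input density + eps)` with a symmetric
#' pseudocount applied to both numerator and denominator, so jointly-zero
#' windows give a ratio of exactly 1 and ratios stay bounded.
#'
#' @param chip,input data.frames from [interval_signal()] (columns
#'   `total`, `length`, `density`), row-aligned.
#' @param eps pseudocount in signal/bp units; must be > 0. Default 0.01.
#' @return data.frame with `chip_density`, `input_density`, `ratio`.
#' @export
normalize_to_input <- function(chip, input, eps = 0.01) {
  stopifnot(eps > 0, nrow(chip) == nrow(input))
  ratio <- (chip$density + eps) / (input$density + eps)
  data.frame(chip_density = chip$density, input_density = input$density,
             ratio = ratio)
}

#' Remove peaks overlapping a blacklist
#'
#' A peak is removed if it overlaps any blacklist interval by at least one
#' base pair (half-open adjacency is not an overlap). Order is preserved.
#'
#' @param peaks a `peak_set`.
#' @param blacklist a `peak_set` (or any interval data.frame) of regions
#'   with artifactually high signal.
#' @return the surviving `peak_set`, original order preserved.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  p <- as.data.frame(peaks)
  bl <- as.data.frame(blacklist)
  if (!nrow(p) || !nrow(bl)) return(peaks)
  hits <- GenomicRanges::findOverlaps(as_granges0(p), as_granges0(bl),
                                      minoverlap = 1L, ignore.strand = TRUE)
  drop <- unique(S4Vectors::queryHits(hits))
  out <- p[setdiff(seq_len(nrow(p)), drop), , drop = FALSE]
  peak_set(out, attr(peaks, "label") %||% "peaks")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Input-normalized signal profile matrix over genes
#'
#' Computes a genes-by-bins matrix of input-normalized signal density,
#' either centered on the TSS (`tss_centered`: `[tss - flank, tss + flank)`
#' split into `nbins` equal bins) or with the gene body rescaled to a fixed
#' number of bins between upstream and downstream flanks
#' (`genebody_scaled`). Rows of minus-strand genes are reversed so
#' transcription always runs left to right; column means form the metagene
#' aggregation profile. No per-row rescaling is applied, so matrices from
#' different time points share one scale.
#'
#' @param track ChIP [coverage_track()].
#' @param input_track input [coverage_track()].
#' @param genes `gene_models` data.frame.
#' @param mode `"tss_centered"` or `"genebody_scaled"`.
#' @param flank flank size in bp (default 5000).
#' @param nbins total number of bins (>= 10). In scaled mode each flank
#'   receives `round(nbins/4)` bins and the body the remainder.
#' @param eps pseudocount for input normalization (see
#'   [normalize_to_input()]).
#' @return numeric matrix (genes x bins, rownames = gene_id) with
#'   attributes `colmeans` (the aggregation profile, NA rows excluded) and
#'   `flagged` (gene_ids whose row is NA: in scaled mode, genes shorter
#'   than the number of body bins).
#' @export
profile_matrix <- function(track, input_track, genes,
                           mode = c("tss_centered", "genebody_scaled"),
                           flank = 5000, nbins = 100, eps = 0.01) {
  mode <- match.arg(mode)
  g <- as.data.frame(genes)
  if (!nrow(g)) stop("profile_matrix: empty gene set", call. = FALSE)
  if (nbins < 10) stop("profile_matrix: nbins must be >= 10", call. = FALSE)
  edges_list <- vector("list", nrow(g))
  flagged <- character(0)
  if (mode == "tss_centered") {
    for (i in seq_len(nrow(g)))
      edges_list[[i]] <- g$tss[i] + seq(-flank, flank, length.out = nbins + 1L)
  } else {
    nb_f <- max(5L, round(nbins / 4))
    nb_body <- nbins - 2L * nb_f
    if (nb_body < 1L) stop("profile_matrix: nbins too small for scaled mode", call. = FALSE)
    for (i in seq_len(nrow(g))) {
      gs <- g$start[i]; ge <- g$end[i]
      if (ge - gs < nb_body) { flagged <- c(flagged, g$gene_id[i]); next }
      edges_list[[i]] <- c(seq(gs - flank, gs, length.out = nb_f + 1L)[-(nb_f + 1L)],
                           seq(gs, ge, length.out = nb_body + 1L)[-(nb_body + 1L)],
                           seq(ge, ge + flank, length.out = nb_f + 1L))
    }
  }
  ok <- which(!vapply(edges_list, is.null, logical(1L)))
  qs <- unlist(lapply(edges_list[ok], function(e) e[-length(e)]))
  qe <- unlist(lapply(edges_list[ok], function(e) e[-1L]))
  qchrom <- rep(g$chrom[ok], each = nbins)
  # windows may run off the chromosome start: off-genome positions carry
  # zero coverage but keep their nominal bin width in the density
  qiv <- data.frame(chrom = qchrom, start = qs, end = qe)
  chip_tot <- .totals_by_chrom(track, qiv)
  inp_tot <- .totals_by_chrom(input_track, qiv)
  wd <- qe - qs
  ratio <- (chip_tot / wd + eps) / (inp_tot / wd + eps)
  mat <- matrix(NA_real_, nrow = nrow(g), ncol = nbins,
                dimnames = list(g$gene_id, NULL))
  mat[ok, ] <- matrix(ratio, ncol = nbins, byrow = TRUE)
  rev_rows <- which(g$strand == "-")
  if (length(rev_rows)) mat[rev_rows, ] <- mat[rev_rows, nbins:1, drop = FALSE]
  structure(mat,
            colmeans = colMeans(mat[setdiff(seq_len(nrow(g)), which(g$gene_id %in% flagged)), ,
                                    drop = FALSE], na.rm = TRUE),
            flagged = flagged, mode = mode)
}

# totals for possibly negative-coordinate query bins (clip to >= 0)
.totals_by_chrom <- function(track, qiv) {
  n <- nrow(qiv)
  total <- numeric(n)
  b <- track$bins
  s <- pmax(qiv$start, 0)
  e <- pmax(qiv$end, 0)
  nonempty <- e > s
  for (ch in unique(qiv$chrom)) {
    qi <- which(qiv$chrom == ch & nonempty)
    if (!length(qi)) next
    bi <- b[b$chrom == ch, , drop = FALSE]
    if (!nrow(bi)) next
    total[qi] <- .signal_totals(bi$start, bi$end, bi$value, s[qi], e[qi])
  }
  total
}

#' Metagene aggregation profile (column means) of a profile matrix
#'
#' @param mat matrix from [profile_matrix()].
#' @return numeric vector of column means (flagged rows excluded).
#' @export
aggregation_profile <- function(mat) attr(mat, "colmeans")
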