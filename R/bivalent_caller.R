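# Bivalent-domain calling from H3K4me3/H3K27me3 peak co-occurrence at
# promoters, gene-set intersection, and paired tag-heatmap matrices.

#' Call bivalent-domain promoters from peak co-occurrence
#'
#' A gene is called bivalent iff its promoter (TSS +/- `half_width`)
#' overlaps at least one peak in EACH of the two peak sets by at least
#' `min_overlap` bp. The reported evidence for each mark is the overlapping
#' peak with the largest overlap (ties broken by leftmost start). At most
#' one call per gene. Peaks are expected to be blacklist-filtered upstream
#' (see [filter_blacklist()]).
#'
#' @param genes `gene_models` data.frame (non-empty).
#' @param k4me3,k27me3 `peak_set`s for the active and repressive mark.
#' @param half_width promoter half-width in bp (default 1000).
#' @param min_overlap minimum overlap in bp (default 1).
#' @return data.frame of class `bivalent_calls`, one row per called gene:
#'   `gene_id`, `chrom`, `tss`, `strand`, `prom_start`, `prom_end`,
#'   `k4_start`, `k4_end`, `k27_start`, `k27_end`; attributes `half_width`,
#'   `min_overlap`.
#' @export
call_bivalent <- function(genes, k4me3, k27me3, half_width = 1000,
                          min_overlap = 1L) {
  g <- as.data.frame(genes)
  if (!nrow(g)) stop("call_bivalent: empty gene list", call. = FALSE)
  prom <- resolve_window(genes, window_spec("TSS", half_width, half_width))
  ev4 <- .best_evidence(prom, k4me3, min_overlap)
  ev27 <- .best_evidence(prom, k27me3, min_overlap)
  called <- which(!is.na(ev4$start) & !is.na(ev27$start))
  out <- data.frame(gene_id = prom$gene_id[called],
                    chrom = prom$chrom[called],
                    tss = g$tss[called],
                    strand = g$strand[called],
                    prom_start = prom$start[called],
                    prom_end = prom$end[called],
                    k4_start = ev4$start[called], k4_end = ev4$end[called],
                    k27_start = ev27$start[called], k27_end = ev27$end[called],
                    stringsAsFactors = FALSE)
  structure(out, half_width = half_width, min_overlap = min_overlap,
            class = c("bivalent_calls", "data.frame"))
}

# For each promoter, the coordinates of the overlapping peak with the
# largest overlap width; ties go to the leftmost peak start. NA when none.
.best_evidence <- function(prom, peaks, min_overlap) {
  p <- as.data.frame(peaks)
  n <- nrow(prom)
  res <- data.frame(start = rep(NA_real_, n), end = rep(NA_real_, n))
  if (!nrow(p)) return(res)
  hits <- GenomicRanges::findOverlaps(as_granges0(prom), as_granges0(p),
                                      minoverlap = as.integer(min_overlap),
                                      ignore.strand = TRUE)
  if (!length(hits)) return(res)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ow <- pmin(prom$end[qh], p$end[sh]) - pmax(prom$start[qh], p$start[sh])
  ord <- order(qh, -ow, p$start[sh])
  first <- ord[!duplicated(qh[ord])]
  res$start[qh[first]] <- p$start[sh[first]]
  res$end[qh[first]] <- p$end[sh[first]]
  res
}

#' Intersect bivalent calls with a gene set
#'
#' Partitions the union of called genes and a gene set (e.g. DEGs) into
#' the Venn classes feeding [overlap_test()].
#'
#' @param calls a `bivalent_calls` data.frame.
#' @param gene_set character vector of gene ids.
#' @return list with `bd_and_set`, `bd_only`, `set_only` (character
#'   vectors, disjoint and exhaustive over the union) and `counts` (named
#'   integer vector including `n_bd` and `n_set`).
#' @export
intersect_with_set <- function(calls, gene_set) {
  bd <- as.character(calls$gene_id)
  gene_set <- unique(as.character(gene_set))
  both <- intersect(bd, gene_set)
  list(bd_and_set = both,
       bd_only = setdiff(bd, gene_set),
       set_only = setdiff(gene_set, bd),
       counts = c(bd_and_set = length(both),
                  bd_only = length(setdiff(bd, gene_set)),
                  set_only = length(setdiff(gene_set, bd)),
                  n_bd = length(bd), n_set = length(gene_set)))
}

#' Paired tag matrices over bivalent calls
#'
#' TSS-centered signal density matrices of the two marks over all called
#' promoters, with identical row order in both matrices (rows sorted by
#' descending H3K4me3 promoter density), the contract for side-by-side
#' tag heatmaps.
#'
#' @param calls a `bivalent_calls` data.frame (non-empty).
#' @param k4_track,k27_track [coverage_track()]s.
#' @param flank flank around the TSS in bp (default 5000).
#' @param nbins number of bins (default 100).
#' @return list with matrices `k4` and `k27` (calls x bins, rownames =
#'   gene_id, same order) and `order` (the gene ids in row order).
#' @export
tag_matrix <- function(calls, k4_track, k27_track, flank = 5000, nbins = 100) {
  cl <- as.data.frame(calls)
  if (!nrow(cl)) stop("tag_matrix: no bivalent calls", call. = FALSE)
  pseudo <- gene_models(data.frame(gene_id = cl$gene_id, chrom = cl$chrom,
                                   start = ifelse(cl$strand == "+", cl$tss, cl$tss - 1L),
                                   end = ifelse(cl$strand == "+", cl$tss + 1L, cl$tss),
                                   strand = cl$strand))
  k4d <- interval_signal(k4_track, cl[, c("chrom", "prom_start", "prom_end")] |>
                           stats::setNames(c("chrom", "start", "end")))$density
  ord <- order(-k4d, cl$gene_id)
  pseudo <- pseudo[ord, , drop = FALSE]
  mk <- function(track) .raw_profile(track, pseudo, flank, nbins)
  list(k4 = mk(k4_track), k27 = mk(k27_track), order = pseudo$gene_id)
}

# raw (not input-normalized) TSS-centered density profile
.raw_profile <- function(track, genes, flank, nbins) {
  g <- as.data.frame(genes)
  edges <- lapply(g$tss, function(t) t + seq(-flank, flank, length.out = nbins + 1L))
  qs <- unlist(lapply(edges, function(e) e[-length(e)]))
  qe <- unlist(lapply(edges, function(e) e[-1L]))
  qiv <- data.frame(chrom = rep(g$chrom, each = nbins), start = qs, end = qe)
  tot <- .totals_by_chrom(track, qiv)
  mat <- matrix(tot / (qe - qs), ncol = nbins, byrow = TRUE,
                dimnames = list(g$gene_id, NULL))
  rev_rows <- which(g$strand == "-")
  if (length(rev_rows)) mat[rev_rows, ] <- mat[rev_rows, nbins:1, drop = FALSE]
  mat
}
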