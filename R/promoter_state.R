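# Promoter chromatin-state clustering (K-means, silhouette-selected K)
# and per-cluster gene-set enrichment.

#' Build the promoter signal matrix for clustering
#'
#' For every gene, computes the input-normalized signal ratio of each mark
#' over the promoter window (TSS +/- `half_width`), then (by default)
#' log2-transforms and z-scores each column. Columns are marks (one track
#' per mark; pass tracks from several time points as separately named
#' entries to cluster on the full time course).
#'
#' @param tracks named list of ChIP [coverage_track()]s, one per column
#'   (e.g. `list(H3K4me3_0h = ..., H3K27me3_0h = ...)`).
#' @param input_track input [coverage_track()].
#' @param genes `gene_models` data.frame.
#' @param half_width promoter half-width in bp; default 1000 (TSS +/- 1 kb).
#' @param eps pseudocount for input normalization.
#' @param transform `"log_z"` (log2 ratio then per-column z-score; default)
#'   or `"raw"` (ratios untouched).
#' @return numeric matrix genes x marks (rownames = gene_id) with attribute
#'   `dropped` counting genes on chromosomes absent from any track (their
#'   rows are removed with a warning).
#' @export
build_promoter_matrix <- function(tracks, input_track, genes, half_width = 1000,
                                  eps = 0.01, transform = c("log_z", "raw")) {
  transform <- match.arg(transform)
  stopifnot(is.list(tracks), length(tracks) >= 1L, !is.null(names(tracks)))
  g <- as.data.frame(genes)
  track_chroms <- Reduce(intersect, lapply(c(tracks, list(input_track)),
                                           function(t) unique(t$bins$chrom)))
  keep <- g$chrom %in% track_chroms
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    warning(n_drop, " gene(s) on chromosomes absent from a track were dropped")
    g <- g[keep, , drop = FALSE]
  }
  if (!nrow(g)) stop("no genes left after chromosome filtering", call. = FALSE)
  prom <- resolve_window(gene_models(g[, c("gene_id", "chrom", "start", "end", "strand")]),
                         window_spec("TSS", half_width, half_width))
  inp <- interval_signal(input_track, prom)
  mat <- vapply(tracks, function(tr) {
    normalize_to_input(interval_signal(tr, prom), inp, eps = eps)$ratio
  }, numeric(nrow(g)))
  mat <- matrix(mat, nrow = nrow(g), dimnames = list(g$gene_id, names(tracks)))
  if (transform == "log_z") {
    lg <- log2(mat)
    zs <- apply(lg, 2L, function(x) {
      s <- stats::sd(x)
      if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
    })
    if (!is.matrix(zs)) zs <- matrix(zs, nrow = nrow(lg))
    dimnames(zs) <- dimnames(mat)
    mat <- zs
  }
  structure(mat, dropped = n_drop, transform = transform)
}

#' Select K by mean silhouette and cluster promoters by K-means
#'
#' For each candidate `k`, runs K-means (Euclidean, `nstart` restarts,
#' seeded) and scores the partition by the mean silhouette width; the
#' returned clustering uses the `k` with the largest mean silhouette.
#' Deterministic given (`mat`, `seed`). The silhouette is computed on the
#' full matrix when it has at most `silhouette_cap` rows, otherwise on a
#' seeded subsample of that size (silhouette cost grows quadratically).
#'
#' @param mat numeric matrix (genes x features), e.g. from
#'   [build_promoter_matrix()].
#' @param k_range candidate cluster counts; default `2:10`.
#' @param seed integer seed recorded in the result.
#' @param nstart K-means restarts per k (default 25).
#' @param silhouette_cap subsample cap for silhouette scoring (default 5000).
#' @return object of class `promoter_clusters`: list with `K`, `labels`
#'   (named integer vector gene_id -> cluster in 1..K), `silhouette_by_k`,
#'   `centers`, `seed`.
#' @export
select_k_and_cluster <- function(mat, k_range = 2:10, seed = 1L, nstart = 25L,
                                 silhouette_cap = 5000L) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (nrow(mat) < max(k_range) * 5L)
    stop("need at least ", max(k_range) * 5L, " rows to scan k up to ",
         max(k_range), call. = FALSE)
  if (all(apply(mat, 2L, function(x) length(unique(x)) == 1L)))
    stop("no cluster structure: all rows identical", call. = FALSE)
  if (nrow(mat) > silhouette_cap) {
    set.seed(seed)
    sil_rows <- sort(sample.int(nrow(mat), silhouette_cap))
  } else sil_rows <- seq_len(nrow(mat))
  d_sub <- stats::dist(mat[sil_rows, , drop = FALSE])
  sil_by_k <- stats::setNames(numeric(length(k_range)), as.character(k_range))
  best <- NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    set.seed(seed + k)
    km <- stats::kmeans(mat, centers = k, nstart = nstart, iter.max = 100L)
    sil <- cluster::silhouette(km$cluster[sil_rows], d_sub)
    sil_by_k[i] <- mean(sil[, "sil_width"])
    if (is.null(best) || sil_by_k[i] > best$sil) best <- list(km = km, k = k, sil = sil_by_k[i])
  }
  structure(list(K = best$k,
                 labels = stats::setNames(as.integer(best$km$cluster), rownames(mat)),
                 silhouette_by_k = sil_by_k,
                 centers = best$km$centers,
                 seed = seed),
            class = "promoter_clusters")
}

#' @export
print.promoter_clusters <- function(x, ...) {
  cat(sprintf("<promoter_clusters> K = %d over %d genes (seed %d)\n",
              x$K, length(x$labels), x$seed))
  print(table(cluster = x$labels))
  invisible(x)
}

#' One-sided enrichment p-value for a 2x2 contingency
#'
#' Probability of observing at least `a` gene-set members in a cluster of
#' size `n_cluster` when `set_size` members are distributed among
#' `n_universe` genes: the upper hypergeometric tail, identical to the
#' one-sided (greater) Fisher exact test on the 2x2 table.
#'
#' @param a observed overlap count (vectorized).
#' @param n_cluster cluster size.
#' @param set_size gene-set size.
#' @param n_universe universe size.
#' @return p-value(s) in (0, 1].
#' @export
hyper_enrichment_p <- function(a, n_cluster, set_size, n_universe) {
  stats::phyper(a - 1, set_size, n_universe - set_size, n_cluster,
                lower.tail = FALSE)
}

#' Gene-set enrichment per cluster (one-sided Fisher exact test)
#'
#' For each cluster, forms the 2x2 table
#' (in-cluster & in-set, in-cluster & out-set; out-cluster & in-set,
#' out-cluster & out-set) and reports the one-sided (greater) exact
#' p-value, the enrichment score observed/expected with
#' `expected = n_cluster * |set| / N`, and the sample odds ratio. P-values
#' are reported raw (no multiple-testing correction) together with the
#' cluster count so users can adjust.
#'
#' @param clusters a `promoter_clusters` object (or a named integer vector
#'   of labels).
#' @param gene_set character vector of gene ids; must be a subset of the
#'   clustered genes and non-empty.
#' @return data.frame with one row per cluster: `cluster`, `n_cluster`,
#'   `n_set_in_cluster`, `expected`, `enrichment_score`, `odds_ratio`, `p`.
#' @export
cluster_enrichment <- function(clusters, gene_set) {
  labels <- if (inherits(clusters, "promoter_clusters")) clusters$labels else clusters
  stopifnot(!is.null(names(labels)))
  if (!length(gene_set)) stop("empty gene_set", call. = FALSE)
  gene_set <- unique(as.character(gene_set))
  if (!all(gene_set %in% names(labels)))
    stop("gene_set contains ids outside the clustered universe", call. = FALSE)
  N <- length(labels)
  S <- length(gene_set)
  in_set <- names(labels) %in% gene_set
  ks <- sort(unique(labels))
  rows <- lapply(ks, function(k) {
    nc <- sum(labels == k)
    a <- sum(labels == k & in_set)
    expected <- nc * S / N
    b <- nc - a; c_ <- S - a; d <- N - nc - c_
    data.frame(cluster = k, n_cluster = nc, n_set_in_cluster = a,
               expected = expected,
               enrichment_score = a / expected,
               odds_ratio = (a * d) / (b * c_),
               p = hyper_enrichment_p(a, nc, S, N))
  })
  do.call(rbind, rows)
}

#' Chi-square test of overlap between two gene sets in a universe
#'
#' Pearson chi-square (no continuity correction by default) on the 2x2
#' table implied by `(n_universe, n_setA, n_setB, n_overlap)`, with the
#' expected overlap under independence `n_setA * n_setB / n_universe`.
#'
#' @param n_universe universe size.
#' @param n_setA,n_setB set sizes.
#' @param n_overlap observed overlap; must not exceed `min(n_setA, n_setB)`.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return list with `chi2`, `p`, `expected`, and `warning` (character,
#'   non-empty when any expected cell is below 1).
#' @export
overlap_test <- function(n_universe, n_setA, n_setB, n_overlap, correct = FALSE) {
  if (n_overlap > min(n_setA, n_setB))
    stop("n_overlap exceeds the smaller set", call. = FALSE)
  if (n_setA > n_universe || n_setB > n_universe)
    stop("set larger than universe", call. = FALSE)
  tab <- matrix(c(n_overlap, n_setA - n_overlap,
                  n_setB - n_overlap, n_universe - n_setA - n_setB + n_overlap),
                nrow = 2L, byrow = TRUE)
  if (any(tab < 0)) stop("inconsistent marginals", call. = FALSE)
  expected_tab <- outer(rowSums(tab), colSums(tab)) / n_universe
  warn <- if (any(expected_tab < 1)) "expected cell count below 1" else ""
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value),
       expected = n_setA * n_setB / n_universe, warning = warn)
}
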