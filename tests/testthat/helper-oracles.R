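# Independent oracles and shared fixtures. Oracles are deliberately
# naive (per-base loops, full enumeration) and never call the code paths
# they check.

# per-base coverage value of a track at integer positions (0-based)
oracle_values_at <- function(track, chrom, positions) {
  b <- track$bins[track$bins$chrom == chrom, , drop = FALSE]
  vapply(positions, function(p) {
    hit <- which(b$start <= p & b$end > p)
    if (length(hit)) b$value[hit] else 0
  }, numeric(1L))
}

# per-base brute-force signal total over [start, end)
oracle_signal_total <- function(track, chrom, start, end) {
  lo <- max(start, 0)
  if (end <= lo) return(0)
  sum(oracle_values_at(track, chrom, seq(lo, end - 1L)))
}

# random coverage track on one chromosome of the given length
random_track <- function(n_bins = 100, chrom = "chrT", chrom_len = 10000,
                         label = "rand", gap_prob = 0.3) {
  edges <- sort(sample.int(chrom_len - 1L, 2L * n_bins))
  starts <- edges[seq(1L, length(edges), by = 2L)]
  ends <- edges[seq(2L, length(edges), by = 2L)]
  keep <- ends > starts & runif(length(starts)) > gap_prob
  coverage_track(data.frame(chrom = chrom, start = starts[keep],
                            end = ends[keep],
                            value = round(runif(sum(keep), 0, 10), 3)),
                 label)
}

uniform_track <- function(value, chrom = "chrT", start = 0, end = 10000,
                          label = "uniform") {
  coverage_track(data.frame(chrom = chrom, start = start, end = end,
                            value = value), label)
}

# exact one-sided enrichment p by enumeration over the overlap support,
# using binomial-coefficient counts of the arrangements
oracle_hyper_p <- function(a, n_cluster, set_size, N) {
  support <- max(0L, n_cluster + set_size - N):min(n_cluster, set_size)
  counts <- choose(set_size, support) * choose(N - set_size, n_cluster - support)
  sum(counts[support >= a]) / choose(N, n_cluster)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  combs <- utils::combn(n1 + n2, n1)
  u_obs <- sum(rank(pool)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(combs, 2L, function(idx) {
    sum(rank(pool)[idx]) - n1 * (n1 + 1) / 2
  })
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# brute-force blacklist filter: O(peaks x blacklist) pairwise overlap
oracle_filter_blacklist <- function(peaks, blacklist) {
  p <- as.data.frame(peaks); bl <- as.data.frame(blacklist)
  keep <- vapply(seq_len(nrow(p)), function(i) {
    !any(bl$chrom == p$chrom[i] & bl$start < p$end[i] & bl$end > p$start[i])
  }, logical(1L))
  p[keep, , drop = FALSE]
}

# brute-force bivalent caller: double loop over genes and peaks
oracle_call_bivalent <- function(genes, k4, k27, half_width) {
  g <- as.data.frame(genes)
  hits <- function(peaks, chrom, s, e) {
    p <- as.data.frame(peaks)
    any(p$chrom == chrom & p$start < e & p$end > s)
  }
  called <- vapply(seq_len(nrow(g)), function(i) {
    s <- max(g$tss[i] - half_width, 0); e <- g$tss[i] + half_width
    hits(k4, g$chrom[i], s, e) && hits(k27, g$chrom[i], s, e)
  }, logical(1L))
  g$gene_id[called]
}

# independently coded DEG classifier: one record at a time, no matrices
oracle_classify_one <- function(fc, fdr, fc_up = 2, fdr_max = 0.1) {
  dirs <- character(3)
  for (j in 1:3) {
    sig <- (fc[j] >= fc_up || fc[j] <= 1 / fc_up) && fdr[j] <= fdr_max
    dirs[j] <- if (!sig) "none" else if (fc[j] >= fc_up) "up" else "down"
  }
  if (all(dirs == "none")) return(list(is_deg = FALSE, class = "none"))
  first <- dirs[dirs != "none"][1]
  cls <- if (!any(dirs == "up")) "down"
    else if (!any(dirs == "down")) { if (dirs[1] == "up") "early_up" else "late_up" }
    else if (first == "down") "down"
    else if (dirs[1] == "up") "early_up" else "late_up"
  list(is_deg = TRUE, class = cls)
}

# one default synthetic bundle shared across test files
.bundle_cache <- new.env(parent = emptyenv())
default_bundle <- function() {
  if (is.null(.bundle_cache$b)) .bundle_cache$b <- synth_generate(synth_config())
  .bundle_cache$b
}
default_fixture_dir <- function() {
  if (is.null(.bundle_cache$dir)) {
    d <- file.path(tempdir(), "bivalomics_fixture")
    write_fixture(default_bundle(), d)
    .bundle_cache$dir <- d
  }
  .bundle_cache$dir
}

hour0_marks <- function(bundle) {
  lapply(bundle$tracks[c("H3K4me2", "H3K4me3", "H3K27ac", "H3K27me3")], `[[`, "0")
}

make_genes <- function(...) gene_models(data.frame(...))
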