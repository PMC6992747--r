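peaks_at <- function(chrom, start, end, label = "pk") {
  peak_set(data.frame(chrom = chrom, start = start, end = end), label)
}

test_that("bivalent calls require both marks at the promoter", {
  g <- make_genes(gene_id = "g1", chrom = "chr1", start = 10000, end = 15000,
                  strand = "+")  # tss 10000, promoter [9000, 11000)
  k4 <- peaks_at("chr1", 9900, 10100)
  k27_far <- peaks_at("chr1", 20000, 20500)
  expect_equal(nrow(call_bivalent(g, k4, k27_far)), 0L)

  k27_near <- peaks_at("chr1", 10500, 10900)
  calls <- call_bivalent(g, k4, k27_near)
  expect_equal(calls$gene_id, "g1")
  expect_equal(calls$k4_start, 9900)
  expect_equal(calls$k27_start, 10500)

  expect_error(call_bivalent(g[0, ], k4, k27_near), "empty gene list")
})

test_that("evidence is the largest-overlap peak, ties to the leftmost", {
  g <- make_genes(gene_id = "g1", chrom = "chr1", start = 10000, end = 15000,
                  strand = "+")
  k4 <- peaks_at("chr1", c(9000, 10000), c(9100, 10800))  # 100 vs 800 bp overlap
  k27 <- peaks_at("chr1", c(9200, 9600), c(9400, 9800))   # 200 bp each: tie
  calls <- call_bivalent(g, k4, k27)
  expect_equal(calls$k4_start, 10000)
  expect_equal(calls$k27_start, 9200)
})

test_that("calling is symmetric in the two marks and monotone in half_width", {
  set.seed(301)
  b <- default_bundle()
  k4 <- filter_blacklist(b$peaks$H3K4me3, b$peaks$blacklist)
  k27 <- filter_blacklist(b$peaks$H3K27me3, b$peaks$blacklist)
  fwd <- call_bivalent(b$genes, k4, k27)
  swp <- call_bivalent(b$genes, k27, k4)
  expect_equal(fwd$gene_id, swp$gene_id)
  expect_equal(fwd$k4_start, swp$k27_start)
  expect_equal(fwd$k27_start, swp$k4_start)

  prev <- character(0)
  for (hw in c(250, 500, 1000, 2000)) {
    cur <- call_bivalent(b$genes, k4, k27, half_width = hw)$gene_id
    expect_true(all(prev %in% cur), info = paste("half_width", hw))
    prev <- cur
  }
})

test_that("calls match the brute-force double loop on random fixtures", {
  set.seed(302)
  n <- 200
  tss <- sort(sample(seq(5000, 5e5, by = 50), n))
  g <- make_genes(gene_id = sprintf("g%03d", 1:n), chrom = "chrR",
                  start = tss, end = tss + 3000, strand = "+")
  mk_peaks <- function(m) {
    s <- sample.int(5e5, m)
    peaks_at("chrR", s, s + sample(100:2000, m, TRUE))
  }
  k4 <- mk_peaks(150); k27 <- mk_peaks(80)
  for (hw in c(500, 1000)) {
    got <- call_bivalent(g, k4, k27, half_width = hw)$gene_id
    expect_equal(got, oracle_call_bivalent(g, k4, k27, hw), info = hw)
  }
})

test_that("planted bivalent promoters are recovered exactly", {
  b <- default_bundle()
  k4 <- filter_blacklist(b$peaks$H3K4me3, b$peaks$blacklist)
  k27 <- filter_blacklist(b$peaks$H3K27me3, b$peaks$blacklist)
  calls <- call_bivalent(b$genes, k4, k27)
  truth <- b$manifest$gene_id[b$manifest$is_bd]
  expect_setequal(calls$gene_id, truth)
})

test_that("set intersection partitions the union and matches set algebra", {
  calls <- structure(data.frame(gene_id = c("a", "b", "c")),
                     class = c("bivalent_calls", "data.frame"))
  r <- intersect_with_set(calls, c("b", "c", "d"))
  expect_setequal(r$bd_and_set, c("b", "c"))
  expect_equal(r$bd_only, "a")
  expect_equal(r$set_only, "d")
  expect_equal(unname(r$counts["bd_and_set"] + r$counts["bd_only"]), 3)

  expect_equal(length(intersect_with_set(calls, c("x", "y"))$bd_and_set), 0L)
  expect_equal(length(intersect_with_set(calls, c("a", "b", "c"))$bd_and_set), 3L)

  set.seed(303)
  for (i in 1:10) {
    bd_ids <- sample(letters, 10)
    set_ids <- sample(letters, 12)
    cl <- structure(data.frame(gene_id = bd_ids),
                    class = c("bivalent_calls", "data.frame"))
    r <- intersect_with_set(cl, set_ids)
    expect_setequal(c(r$bd_and_set, r$bd_only, r$set_only), union(bd_ids, set_ids))
    expect_equal(length(intersect(r$bd_only, r$set_only)), 0L)
    expect_setequal(r$bd_and_set, intersect(bd_ids, set_ids))
  }
})

test_that("tag matrices share row order and show centered enrichment", {
  b <- default_bundle()
  k4t <- b$tracks$H3K4me3[["0"]]
  k27t <- b$tracks$H3K27me3[["0"]]
  calls <- call_bivalent(b$genes,
                         filter_blacklist(b$peaks$H3K4me3, b$peaks$blacklist),
                         filter_blacklist(b$peaks$H3K27me3, b$peaks$blacklist))
  tm <- tag_matrix(calls, k4t, k27t, flank = 3000, nbins = 60)
  expect_identical(rownames(tm$k4), rownames(tm$k27))
  expect_identical(rownames(tm$k4), tm$order)
  # rows sorted by descending promoter H3K4me3 density
  prom_d <- interval_signal(k4t, data.frame(chrom = calls$chrom,
                                            start = calls$prom_start,
                                            end = calls$prom_end))$density
  expect_false(is.unsorted(rev(prom_d[match(tm$order, calls$gene_id)])))
  # centered enrichment for both marks
  for (m in tm[c("k4", "k27")]) {
    cm <- colMeans(m)
    expect_gt(mean(cm[29:32]), mean(cm[c(1:4, 57:60)]))
  }

  u <- coverage_track(data.frame(chrom = c("chrS1", "chrS2"), start = 0,
                                 end = 5e6, value = 2), "u")
  tmu <- tag_matrix(calls[1:5, ], u, u, flank = 1000, nbins = 20)
  expect_equal(unname(tmu$k4), matrix(2, 5, 20))
})

test_that("bivalent genes have lower planted expression than other expressed genes", {
  b <- default_bundle()
  expr <- b$expression
  expressed <- expressed_filter(expr)
  bd <- b$manifest$gene_id[b$manifest$is_bd]
  f0 <- expr$fpkm_0h[match(expressed, expr$gene_id)]
  is_bd_e <- expressed %in% bd
  expect_lt(mean(f0[is_bd_e]), mean(f0[!is_bd_e]))
  expect_lt(stats::wilcox.test(f0[is_bd_e], f0[!is_bd_e])$p.value, 1e-6)
})
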