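test_that("windows resolve strand-aware and clip at the chromosome start", {
  g <- make_genes(gene_id = c("plus", "minus"), chrom = "chr1",
                  start = c(1000, 200), end = c(5000, 1000),
                  strand = c("+", "-"))
  tssw <- resolve_window(g, window_spec("TSS", 50, 300))
  expect_equal(tssw$start, c(950, 700))   # minus gene tss = 1000 mirrored
  expect_equal(tssw$end, c(1300, 1050))

  prom <- resolve_window(g[1, ], window_spec("TSS", 1000, 1000))
  expect_equal(c(prom$start, prom$end), c(0, 2000))
  expect_equal(prom$end - prom$start, 2000)

  near0 <- make_genes(gene_id = "edge", chrom = "chr1", start = 100, end = 600,
                      strand = "+")
  w <- resolve_window(near0, window_spec("TSS", 1000, 50))
  expect_equal(w$start, 0)

  offchrom <- make_genes(gene_id = "off", chrom = "chr1", start = 10, end = 500,
                         strand = "+")
  expect_error(resolve_window(offchrom, window_spec("TSS", 1000, -900)),
               "off-chromosome")
})

test_that("interval_signal matches direct computation on constructed tracks", {
  tr <- uniform_track(2, start = 0, end = 1000)
  s <- interval_signal(tr, data.frame(chrom = "chrT", start = 100, end = 200))
  expect_equal(s$total, 200)
  expect_equal(s$density, 2)

  none <- interval_signal(tr, data.frame(chrom = "chrT", start = 5000, end = 6000))
  expect_equal(none$total, 0)
  expect_equal(none$density, 0)

  other <- interval_signal(tr, data.frame(chrom = "chrX", start = 0, end = 10))
  expect_equal(other$total, 0)
})

test_that("interval_signal equals the per-base oracle on random fixtures", {
  set.seed(101)
  tr <- random_track(n_bins = 500, chrom_len = 10000)
  qs <- sort(sample.int(9999, 40))
  qe <- pmin(qs + sample.int(500, 40), 10000L)
  ok <- qe > qs
  got <- interval_signal(tr, data.frame(chrom = "chrT", start = qs[ok], end = qe[ok]))
  want <- mapply(function(s, e) oracle_signal_total(tr, "chrT", s, e), qs[ok], qe[ok])
  expect_equal(got$total, unname(want), tolerance = 1e-9)
})

test_that("interval_signal is additive over adjacent windows", {
  set.seed(102)
  tr <- random_track(n_bins = 200, chrom_len = 10000)
  for (i in 1:20) {
    abc <- sort(sample.int(10000, 3))
    tot <- function(s, e) interval_signal(tr, data.frame(chrom = "chrT", start = s, end = e))$total
    expect_equal(tot(abc[1], abc[3]), tot(abc[1], abc[2]) + tot(abc[2], abc[3]),
                 tolerance = 1e-9)
  }
})

test_that("input normalization applies a symmetric pseudocount", {
  sv <- function(d) data.frame(total = d * 100, length = 100, density = d)
  expect_equal(normalize_to_input(sv(3), sv(3))$ratio, 1)
  expect_equal(normalize_to_input(sv(0), sv(0))$ratio, 1)
  expect_equal(normalize_to_input(sv(4), sv(2), eps = 0.01)$ratio, 4.01 / 2.01)
  # invariance under common scaling as eps -> 0
  for (c_ in c(0.1, 10)) {
    r <- normalize_to_input(sv(4 * c_), sv(2 * c_), eps = 1e-9)$ratio
    expect_equal(r, 2, tolerance = 1e-6)
  }
  expect_error(normalize_to_input(sv(1), sv(1), eps = 0), "eps > 0")
})

test_that("blacklist filtering removes any >= 1 bp overlap, keeps adjacency", {
  pk <- peak_set(data.frame(chrom = "chr1", start = c(100, 100), end = c(200, 200)))
  bl1 <- peak_set(data.frame(chrom = "chr1", start = 150, end = 160), "bl")
  expect_equal(nrow(filter_blacklist(pk[1, ], bl1)), 0L)
  bl2 <- peak_set(data.frame(chrom = "chr1", start = 200, end = 300), "bl")
  expect_equal(nrow(filter_blacklist(pk[1, ], bl2)), 1L)
})

test_that("blacklist filtering matches the brute-force oracle and is idempotent", {
  set.seed(103)
  n <- 200
  s <- sample.int(1e5, n)
  pk <- peak_set(data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                            start = s, end = s + sample.int(300, n)), "peaks")
  bs <- sample.int(1e5, 30)
  bl <- peak_set(data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                            start = bs, end = bs + sample.int(1000, 30)), "bl")
  got <- filter_blacklist(pk, bl)
  want <- oracle_filter_blacklist(pk, bl)
  expect_equal(got$start, want$start)
  expect_equal(got$chrom, want$chrom)
  expect_true(all(got$start %in% pk$start))            # subset of input
  expect_equal(as.data.frame(filter_blacklist(got, bl)), as.data.frame(got))
})

test_that("profile_matrix reproduces constructed signal shapes", {
  chip <- uniform_track(3, end = 60000)
  inp <- uniform_track(3, end = 60000)
  g <- make_genes(gene_id = c("a", "b"), chrom = "chrT",
                  start = c(20000, 40000), end = c(26000, 46000),
                  strand = c("+", "-"))
  for (mode in c("tss_centered", "genebody_scaled")) {
    m <- profile_matrix(chip, inp, g, mode = mode, flank = 2000, nbins = 40)
    expect_equal(unname(m[, ]), matrix(1, 2, 40), tolerance = 1e-12, info = mode)
  }

  # step signal: 0 upstream of the TSS, 5 downstream; uniform input
  step <- coverage_track(data.frame(chrom = "chrT", start = 20000, end = 60000,
                                    value = 5), "step")
  inp1 <- uniform_track(1, end = 60000)
  m <- profile_matrix(step, inp1, g[1, ], mode = "tss_centered",
                      flank = 2000, nbins = 40, eps = 0.01)
  expect_equal(unname(m[1, 20]), 0.01 / 1.01, tolerance = 1e-9)  # last upstream bin
  expect_equal(unname(m[1, 21]), 5.01 / 1.01, tolerance = 1e-9)  # first downstream bin
})

test_that("profile rows are strand-symmetric", {
  set.seed(104)
  tr <- random_track(n_bins = 400, chrom_len = 60000)
  inp <- uniform_track(1, end = 60000)
  # a minus-strand gene and its mirrored plus-strand twin share the profile
  gm <- make_genes(gene_id = "m", chrom = "chrT", start = 20000, end = 30000,
                   strand = "-")
  gp <- make_genes(gene_id = "p", chrom = "chrT", start = 20000, end = 30000,
                   strand = "+")
  for (mode in c("tss_centered", "genebody_scaled")) {
    mm <- profile_matrix(tr, inp, gm, mode = mode, nbins = 50)
    mp <- profile_matrix(tr, inp, gp, mode = mode, nbins = 50)
    if (mode == "tss_centered") {
      # minus gene anchors at the other end; mirror the track instead
      mirror <- coverage_track(data.frame(chrom = "chrT",
                                          start = 60000 - rev(tr$bins$end),
                                          end = 60000 - rev(tr$bins$start),
                                          value = rev(tr$bins$value)), "mir")
      gmir <- make_genes(gene_id = "m", chrom = "chrT", start = 30000,
                         end = 40000, strand = "+")
      mmir <- profile_matrix(mirror, inp, gmir, mode = mode, nbins = 50)
      expect_equal(unname(mm[1, ]), unname(mmir[1, ]), tolerance = 1e-9)
    } else {
      expect_equal(unname(mm[1, ]), unname(rev(mp[1, ])), tolerance = 1e-9)
    }
  }
})

test_that("profile_matrix flags genes too short for the scaled body", {
  tr <- uniform_track(1, end = 60000)
  g <- make_genes(gene_id = c("tiny", "okg"), chrom = "chrT",
                  start = c(20000, 40000), end = c(20010, 46000),
                  strand = "+")
  m <- profile_matrix(tr, tr, g, mode = "genebody_scaled", nbins = 40)
  expect_equal(attr(m, "flagged"), "tiny")
  expect_true(all(is.na(m["tiny", ])))
  expect_false(anyNA(m["okg", ]))
})

test_that("metagene column means peak at the TSS for planted TSS pulses", {
  set.seed(105)
  n <- 50
  tss <- seq(20000, by = 12000, length.out = n)
  g <- make_genes(gene_id = sprintf("g%02d", 1:n), chrom = "chrT",
                  start = tss, end = tss + 5000,
                  strand = "+")
  chip_bins <- data.frame(chrom = "chrT", start = tss - 200, end = tss + 200,
                          value = runif(n, 4, 8))
  chip <- coverage_track(chip_bins, "pulse")
  inp <- uniform_track(1, end = max(tss) + 20000)
  m <- profile_matrix(chip, inp, g, mode = "tss_centered", flank = 5000,
                      nbins = 100)
  peak_bin <- which.max(aggregation_profile(m))
  expect_lte(abs(peak_bin - 50.5), 1.5)  # within one bin of the center
})
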