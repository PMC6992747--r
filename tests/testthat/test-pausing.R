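test_that("PI is 1 on uniform tracks and matches hand-computed step tracks", {
  u <- uniform_track(2, end = 60000)
  inp <- uniform_track(1, end = 60000)
  g <- make_genes(gene_id = "g1", chrom = "chrT", start = 20000, end = 30000,
                  strand = "+")
  expect_equal(pausing_index(u, inp, g)$pi, 1, tolerance = 1e-12)

  # TSS window density 10, body density 1, uniform input
  step <- coverage_track(data.frame(chrom = "chrT",
                                    start = c(0, 19950, 20300),
                                    end = c(19950, 20300, 60000),
                                    value = c(0, 10, 1)), "step")
  pr <- pausing_index(step, inp, g, eps = 1e-9)
  expect_equal(pr$pi, 10, tolerance = 1e-6)
})

test_that("PI windows match the per-base oracle", {
  set.seed(501)
  tr <- random_track(n_bins = 800, chrom_len = 2e5)
  inp <- uniform_track(1, end = 2e5, label = "inp")
  tss <- sample(seq(10000, 150000, by = 100), 100)
  g <- make_genes(gene_id = sprintf("g%03d", 1:100), chrom = "chrT",
                  start = tss, end = tss + sample(seq(3000, 20000, 100), 100, TRUE),
                  strand = sample(c("+", "-"), 100, TRUE))
  g <- gene_models(as.data.frame(g)[, c("gene_id", "chrom", "start", "end", "strand")])
  eps <- 0.01
  pr <- pausing_index(tr, inp, g, eps = eps)
  want <- vapply(seq_len(nrow(g)), function(i) {
    if (g$strand[i] == "+") {
      tw <- c(g$tss[i] - 50, g$tss[i] + 300)
      bw <- c(g$tss[i] + 300, g$tes[i] + 2000)
    } else {
      tw <- c(g$tss[i] - 300, g$tss[i] + 50)
      bw <- c(g$tes[i] - 2000, g$tss[i] - 300)
    }
    td <- oracle_signal_total(tr, "chrT", tw[1], tw[2]) / (tw[2] - tw[1])
    bd <- oracle_signal_total(tr, "chrT", bw[1], bw[2]) / (bw[2] - bw[1])
    ((td + eps) / (1 + eps)) / ((bd + eps) / (1 + eps))
  }, numeric(1))
  ok <- pr$flag == "ok"
  expect_gt(sum(ok), 90)
  expect_equal(pr$pi[ok], want[ok], tolerance = 1e-9)
})

test_that("PI is invariant to global track scaling and strand mirroring", {
  set.seed(502)
  tr <- random_track(n_bins = 300, chrom_len = 60000)
  inp <- uniform_track(1, end = 60000)
  g <- make_genes(gene_id = "g1", chrom = "chrT", start = 20000, end = 30000,
                  strand = "+")
  base <- pausing_index(tr, inp, g, eps = 1e-9)$pi
  for (c_ in c(0.1, 10)) {
    sc <- coverage_track(transform(tr$bins, value = value * c_), "scaled")
    expect_equal(pausing_index(sc, inp, g, eps = 1e-9)$pi, base,
                 tolerance = 1e-6)
  }

  L <- 60000
  mirror <- coverage_track(data.frame(chrom = "chrT",
                                      start = L - rev(tr$bins$end),
                                      end = L - rev(tr$bins$start),
                                      value = rev(tr$bins$value)), "mir")
  gm <- make_genes(gene_id = "g1m", chrom = "chrT", start = L - 30000,
                   end = L - 20000, strand = "-")
  expect_equal(pausing_index(mirror, inp, gm, eps = 1e-9)$pi, base,
               tolerance = 1e-9)
})

test_that("degenerate records are flagged rather than fabricated", {
  inp <- uniform_track(1, end = 60000)
  g <- make_genes(gene_id = "g1", chrom = "chrT", start = 20000, end = 30000,
                  strand = "+")
  # no RNAPII signal anywhere: no_signal flag, PI undefined
  empty <- coverage_track(data.frame(chrom = "chrT", start = 0, end = 60000,
                                     value = 0), "empty")
  pr <- pausing_index(empty, inp, g)
  expect_equal(pr$flag, "no_signal")
  expect_true(is.na(pr$pi))

  # all signal inside the TSS window: body floored at eps, PI very large
  pulse <- coverage_track(data.frame(chrom = "chrT", start = 19950, end = 20300,
                                     value = 50), "pulse")
  pr2 <- pausing_index(pulse, inp, g, eps = 0.01)
  expect_equal(pr2$flag, "ok")
  expect_gt(pr2$pi, 100)

  # body window shorter than the minimum is flagged short_gene
  pr3 <- pausing_index(pulse, inp, g, body_end_offset = 0, min_body = 20000)
  expect_equal(pr3$flag, "short_gene")

  # the literal upstream body-start reading is selectable
  pr4 <- pausing_index(pulse, inp, g, body_start_offset = -300, eps = 0.01)
  expect_lt(pr4$pi, pr2$pi)  # body now includes the TSS pulse
})

test_that("PI time course reports trajectories and pause-release fractions", {
  b <- default_bundle()
  recs <- lapply(c("0", "1", "4", "12"), function(tp) {
    pausing_index(b$tracks$RNAPII[[tp]], b$tracks$input[[tp]], b$genes)
  })
  names(recs) <- c("0", "1", "4", "12")
  release <- b$manifest$gene_id[b$manifest$is_release]
  tc <- pi_timecourse(recs, release_set = release)
  expect_equal(tc$summary$fraction_decreasing, 1.0)
  # non-release genes: no systematic PI shift at 1 h
  nonrel <- setdiff(tc$table$gene_id, release)
  expect_lt(abs(median(tc$table$dlog2_1v0[tc$table$gene_id %in% nonrel])), 0.1)

  # identical tracks at all time points: all deltas zero
  same <- list(`0` = recs[["0"]], `1` = recs[["0"]])
  tc0 <- pi_timecourse(same)
  expect_equal(tc0$table$dlog2_1v0, rep(0, nrow(tc0$table)))

  expect_error(pi_timecourse(list(`0` = recs[["0"]],
                                  `1` = recs[["1"]][1:10, ])),
               "different gene sets")
})

test_that("planted pausing medians are recovered from the tracks", {
  b <- default_bundle()
  pr <- pausing_index(b$tracks$RNAPII[["0"]], b$tracks$input[["0"]], b$genes)
  m <- b$manifest
  rel_err <- abs(pr$pi / m$pi_0h - 1)
  expect_lt(median(rel_err, na.rm = TRUE), 0.02)
  expect_lt(max(rel_err, na.rm = TRUE), 0.05)
  paused_pi <- pr$pi[m$is_paused]
  expect_lt(abs(median(paused_pi) / median(m$pi_0h[m$is_paused]) - 1), 0.05)
})

test_that("metagene profiles are identical for identical tracks and show release", {
  b <- default_bundle()
  up_bd <- b$manifest$gene_id[b$manifest$is_release]
  genes_sub <- b$genes[b$genes$gene_id %in% up_bd, ]
  mg <- metagene_rnapii(b$tracks$RNAPII[c("0", "1")], b$tracks$input[c("0", "1")],
                        genes_sub, flank = 2000, nbins = 40)
  body_bins <- 15:25
  expect_gt(mean(mg$aggregate["1", body_bins]), mean(mg$aggregate["0", body_bins]))

  same <- metagene_rnapii(list(a = b$tracks$RNAPII[["0"]], b = b$tracks$RNAPII[["0"]]),
                          list(a = b$tracks$input[["0"]], b = b$tracks$input[["0"]]),
                          genes_sub, flank = 2000, nbins = 40)
  expect_equal(same$aggregate["a", ], same$aggregate["b", ])
  expect_error(metagene_rnapii(b$tracks$RNAPII[c("0", "1")],
                               b$tracks$input[c("0", "1")], b$genes[0, ]),
               "empty gene set")
})
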