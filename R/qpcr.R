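# ChIP-qPCR chromatin occupancy and two-group comparisons.

#' Chromatin occupancy from ChIP-qPCR Ct values
#'
#' Occupancy of a test site relative to a control site:
#' `2 ^ (dCt_test - dCt_ctrl)` where `dCt = ct_chip - ct_input` at each
#' site (the `"site"` convention, the formula as commonly printed for this
#' assay). Under this sign convention stronger enrichment (lower ChIP Ct at
#' the test site) gives occupancy < 1; the conventional delta-delta-Ct
#' sign, `2 ^ -(dCt_test - dCt_ctrl)`, is selectable with
#' `convention = "ddct"`.
#'
#' Occupancy is invariant to adding a constant to both ChIP Ct values (or
#' both input Ct values) of test and control, and self-comparison gives 1.
#'
#' @param test,control lists or one-row data.frames with `ct_chip` and
#'   `ct_input` (vectorized over replicates); `control` must be the
#'   control site.
#' @param convention `"site"` (as printed; default) or `"ddct"`.
#' @return numeric occupancy value(s).
#' @export
chromatin_occupancy <- function(test, control, convention = c("site", "ddct")) {
  convention <- match.arg(convention)
  if (is.null(control) || is.null(control$ct_chip))
    stop("chromatin_occupancy: missing control measurement", call. = FALSE)
  d <- (test$ct_chip - test$ct_input) - (control$ct_chip - control$ct_input)
  if (convention == "ddct") d <- -d
  2^d
}

#' Summarize a ChIP-qPCR Ct table as per-site occupancies
#'
#' Pairs each test-site replicate with the control-site measurement of the
#' same replicate and reports per-replicate occupancies plus their
#' geometric mean (occupancy is a log-scale quantity).
#'
#' @param ct data.frame as returned by [read_ct_table()]; exactly one
#'   control site is required.
#' @param convention see [chromatin_occupancy()].
#' @return list with `per_replicate` (data.frame: `site_id`, `replicate`,
#'   `occupancy`) and `per_site` (data.frame: `site_id`, `n`,
#'   `geom_mean_occupancy`).
#' @export
occupancy_table <- function(ct, convention = c("site", "ddct")) {
  convention <- match.arg(convention)
  ct <- validate_ct_table(as.data.frame(ct))
  ctrl_sites <- unique(ct$site_id[ct$role == "control"])
  if (length(ctrl_sites) != 1L)
    stop("occupancy_table: exactly one control site required, found ",
         length(ctrl_sites), call. = FALSE)
  ctrl <- ct[ct$role == "control", ]
  test <- ct[ct$role == "test", ]
  m <- match(test$replicate, ctrl$replicate)
  if (any(is.na(m)))
    stop("occupancy_table: test replicate without matching control replicate",
         call. = FALSE)
  occ <- chromatin_occupancy(test, ctrl[m, ], convention = convention)
  per_rep <- data.frame(site_id = test$site_id, replicate = test$replicate,
                        occupancy = occ, stringsAsFactors = FALSE)
  gm <- vapply(split(per_rep$occupancy, per_rep$site_id),
               function(x) exp(mean(log(x))), numeric(1L))
  list(per_replicate = per_rep,
       per_site = data.frame(site_id = names(gm), n = as.integer(table(per_rep$site_id)[names(gm)]),
                             geom_mean_occupancy = unname(gm),
                             stringsAsFactors = FALSE))
}

#' Compare two groups of occupancies
#'
#' Two-sided Mann-Whitney U test (exact when both groups have at most 8
#' observations and no ties; with ties the mid-rank normal approximation
#' is used with a warning) or a two-tailed Student's t-test (equal
#' variances).
#'
#' @param a,b numeric vectors, each of length >= 3.
#' @param test `"mann_whitney"` (default) or `"t_two_tailed"`.
#' @return list with `statistic`, `p`, `method`.
#' @export
group_compare <- function(a, b, test = c("mann_whitney", "t_two_tailed")) {
  test <- match.arg(test)
  if (length(a) < 3L || length(b) < 3L)
    stop("group_compare: each group needs n >= 3", call. = FALSE)
  if (test == "mann_whitney") {
    exact <- max(length(a), length(b)) <= 8L
    ht <- stats::wilcox.test(a, b, exact = exact, correct = TRUE)
    list(statistic = unname(ht$statistic), p = ht$p.value, method = ht$method)
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p = ht$p.value, method = ht$method)
  }
}
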