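# Expressed-gene filter, DEG rule over the stimulation time course, and
# temporal classification (early/late upregulated, downregulated).

#' Expressed-gene filter
#'
#' A gene is expressed iff its FPKM reaches `threshold` at ANY of the four
#' time points (boundary inclusive).
#'
#' @param expr expression data.frame (see [read_expression()]).
#' @param threshold FPKM threshold; default 1.
#' @return character vector of expressed gene ids.
#' @export
expressed_filter <- function(expr, threshold = 1) {
  fpkm <- as.matrix(expr[paste0("fpkm_", c(0, 1, 4, 12), "h")])
  expr$gene_id[apply(fpkm, 1L, max) >= threshold]
}

#' Classify differential expression and temporal response
#'
#' A comparison (1 vs 0, 4 vs 0, 12 vs 0 h) is significant iff the fold
#' change passes the threshold in either direction (`fc >= fc_up` for up,
#' `fc <= fc_down` for down; boundaries inclusive) AND `fdr <= fdr_max`
#' (inclusive). A gene is a DEG iff any comparison is significant. The
#' temporal class is: `early_up` iff significantly up at 1 h; `late_up`
#' iff up at 4 or 12 h but not at 1 h; `down` iff any down comparison and
#' no up comparison; a gene both up and down across comparisons is
#' assigned by its earliest significant comparison. Non-DEGs get `none`.
#'
#' @param expr expression data.frame (see [read_expression()]).
#' @param fc_up up-regulation fold-change threshold (default 2).
#' @param fc_down down-regulation threshold (default `1 / fc_up`).
#' @param fdr_max FDR threshold (default 0.1).
#' @param fpkm_min expressed-gene FPKM threshold (default 1).
#' @return data.frame with `gene_id`, `is_expressed`, `is_deg`,
#'   `dir_1v0`, `dir_4v0`, `dir_12v0` (each `"up"`, `"down"` or `"none"`),
#'   `temporal_class` (`"early_up"`, `"late_up"`, `"down"`, `"none"`).
#' @export
classify_expression <- function(expr, fc_up = 2, fc_down = 1 / fc_up,
                                fdr_max = 0.1, fpkm_min = 1) {
  expr <- validate_expression(as.data.frame(expr))
  comps <- c("1v0", "4v0", "12v0")
  fc <- as.matrix(expr[paste0("fc_", comps)])
  fdr <- as.matrix(expr[paste0("fdr_", comps)])
  up <- fc >= fc_up & fdr <= fdr_max
  down <- fc <= fc_down & fdr <= fdr_max
  dir <- matrix("none", nrow(expr), 3L, dimnames = list(NULL, comps))
  dir[up] <- "up"
  dir[down] <- "down"
  sig <- up | down
  is_deg <- rowSums(sig) > 0
  temporal <- rep("none", nrow(expr))
  for (i in which(is_deg)) {
    any_up <- any(dir[i, ] == "up"); any_down <- any(dir[i, ] == "down")
    d <- if (any_up && any_down) dir[i, which(sig[i, ])[1L]]  # earliest significant
         else if (any_up) "up" else "down"
    temporal[i] <- if (d == "down") "down"
                   else if (dir[i, "1v0"] == "up") "early_up" else "late_up"
  }
  data.frame(gene_id = expr$gene_id,
             is_expressed = expr$gene_id %in% expressed_filter(expr, fpkm_min),
             is_deg = is_deg,
             dir_1v0 = dir[, "1v0"], dir_4v0 = dir[, "4v0"], dir_12v0 = dir[, "12v0"],
             temporal_class = temporal,
             stringsAsFactors = FALSE)
}
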