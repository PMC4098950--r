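#' Threshold abundance ratios into sample enrichment classes
#'
#' Vectorized fold-change test for quantitative datasets: a ratio strictly
#' above `qc$case_ratio_min` is enriched in the case sample (`"as_case"`),
#' strictly below `qc$control_ratio_max` enriched in the control sample
#' (`"as_control"`), anything in the neutral band — including a ratio of
#' exactly 1 — is `"neither"`. Missing or non-positive ratios are `"neither"`
#' as well (they carry no usable quantitative evidence).
#'
#' @param ratio Numeric vector of case/control abundance ratios.
#' @param qc A [quant_config()].
#' @return Character vector in `c("as_case", "as_control", "neither")`.
#' @examples
#' quantify_presence(c(2.5, 1.5, 1.0, 0.5), quant_config())
#' @export
quantify_presence <- function(ratio, qc = quant_config()) {
  stopifnot(inherits(qc, "quant_config"))
  out <- rep("neither", length(ratio))
  ok <- !is.na(ratio) & ratio > 0
  out[ok & ratio > qc$case_ratio_min] <- "as_case"
  out[ok & ratio < qc$control_ratio_max] <- "as_control"
  out
}

#' Relabel hits by their abundance ratio (quantitative mode)
#'
#' Rewrites the sample labels of a pooled quantitative dataset so that the
#' qualitative consensus machinery applies unchanged: peptides enriched in
#' the case sample are treated as if they had been identified in a
#' qualitative case sample, control-enriched peptides likewise, and peptides
#' in the neutral band are duplicated into both samples so that their events
#' classify as common. Hits without a positive ratio trigger a
#' `MISSING_RATIO` warning and fall into the neutral band.
#'
#' @param hits Hit tibble (typically pooled, labels are overwritten).
#' @param qc A [quant_config()].
#' @return Relabeled hit tibble (neutral-band hits appear twice, once per
#'   sample) with attribute `"warnings"`.
#' @export
apply_quant_mode <- function(hits, qc = quant_config()) {
  cls <- quantify_presence(hits$ratio, qc)
  missing <- is.na(hits$ratio) | hits$ratio <= 0
  warnings <- if (any(missing)) {
    warn_tbl("MISSING_RATIO", sprintf(
      "peptide %s (%s, %s): missing or non-positive abundance ratio; treated as unchanged between samples",
      hits$peptide[missing], hits$engine[missing], hits$file_id[missing]))
  } else {
    new_warning_tbl()
  }

  case_part <- hits[cls != "as_control", , drop = FALSE]
  case_part$sample_label <- "case"
  control_part <- hits[cls != "as_case", , drop = FALSE]
  control_part$sample_label <- "control"
  out <- bind_rows(case_part, control_part)
  attr(out, "warnings") <- warnings
  out
}
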