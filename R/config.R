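#' Score-filter configuration
#'
#' Bundles the per-engine quality-score cutoffs and the modification settings
#' applied to parsed peptide-spectrum matches (PSMs). The defaults are the
#' thresholds used throughout the package's worked examples: Mascot expect
#' value at most 0.01 and Paragon peptide confidence at least 99%. A threshold
#' left `NULL` is not applied, so `filter_config(mascot_expect_max = NULL,
#' paragon_confidence_min = NULL)` passes every hit through unchanged.
#'
#' @param mascot_expect_max Maximum Mascot expectation value a hit may carry
#'   (smaller is better). `NULL` disables the cutoff.
#' @param mascot_ion_score_min Optional minimum Mascot ion score. When both
#'   Mascot thresholds are set they are applied conjunctively.
#' @param paragon_confidence_min Minimum Paragon peptide confidence, percent
#'   in `[0, 100]`. `NULL` disables the cutoff.
#' @param localization_score_min Optional minimum modification-site
#'   localization score (e.g. a Mascot delta or PhosphoRS score passed through
#'   by the exporting software). Applies to every engine; hits below the
#'   threshold, or lacking the score while the threshold is set, are dropped.
#' @param target_residues Characters of residues whose modifications are
#'   considered, default serine, threonine, tyrosine and lysine.
#' @param mod_types Modification types considered, subset of
#'   `c("phospho", "acetyl")`.
#' @return A list of class `"filter_config"`.
#' @examples
#' filter_config()
#' filter_config(mascot_ion_score_min = 25, mod_types = "phospho")
#' @export
filter_config <- function(mascot_expect_max = 0.01,
                          mascot_ion_score_min = NULL,
                          paragon_confidence_min = 99,
                          localization_score_min = NULL,
                          target_residues = c("S", "T", "Y", "K"),
                          mod_types = c("phospho", "acetyl")) {
  check_threshold <- function(x, name) {
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1L || !is.finite(x))) {
      abort(sprintf("`%s` must be NULL or a single finite number.", name))
    }
  }
  check_threshold(mascot_expect_max, "mascot_expect_max")
  check_threshold(mascot_ion_score_min, "mascot_ion_score_min")
  check_threshold(paragon_confidence_min, "paragon_confidence_min")
  check_threshold(localization_score_min, "localization_score_min")
  if (!is.null(paragon_confidence_min) &&
      (paragon_confidence_min < 0 || paragon_confidence_min > 100)) {
    abort("`paragon_confidence_min` must lie in [0, 100].")
  }
  target_residues <- toupper(unique(as.character(target_residues)))
  if (length(target_residues) == 0L) {
    abort("`target_residues` must name at least one residue.")
  }
  mod_types <- match.arg(mod_types, c("phospho", "acetyl"), several.ok = TRUE)
  structure(
    list(
      mascot_expect_max = mascot_expect_max,
      mascot_ion_score_min = mascot_ion_score_min,
      paragon_confidence_min = paragon_confidence_min,
      localization_score_min = localization_score_min,
      target_residues = target_residues,
      mod_types = mod_types
    ),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "<off>" else format(v)
  cat("<filter_config>\n")
  cat("  mascot expect <=        ", fmt(x$mascot_expect_max), "\n")
  cat("  mascot ion score >=     ", fmt(x$mascot_ion_score_min), "\n")
  cat("  paragon confidence >=   ", fmt(x$paragon_confidence_min), "\n")
  cat("  localization score >=   ", fmt(x$localization_score_min), "\n")
  cat("  target residues:        ", paste(x$target_residues, collapse = ""), "\n")
  cat("  modification types:     ", paste(x$mod_types, collapse = ", "), "\n")
  invisible(x)
}

#' Quantitative-mode fold-change thresholds
#'
#' In quantitative experiments (iTRAQ/SILAC style) the case and control
#' samples are pooled before the database search and each peptide carries a
#' case/control abundance ratio instead of a sample label. A peptide whose
#' ratio exceeds `case_ratio_min` is treated as if it had been identified
#' only in the case sample; one below `control_ratio_max` as if only in the
#' control sample; ratios in the neutral band are treated as present in both
#' samples, so their events come out common. Defaults are sqrt(2) and
#' 1/sqrt(2), i.e. a two-fold difference split symmetrically on the log
#' scale.
#'
#' @param case_ratio_min Ratios strictly above this are enriched in case;
#'   must exceed 1.
#' @param control_ratio_max Ratios strictly below this are enriched in
#'   control; must lie in (0, 1).
#' @return A list of class `"quant_config"`.
#' @examples
#' quant_config()
#' quant_config(case_ratio_min = 2, control_ratio_max = 0.5)
#' @export
quant_config <- function(case_ratio_min = 1.414, control_ratio_max = 0.707) {
  if (!is.numeric(case_ratio_min) || length(case_ratio_min) != 1L ||
      !is.finite(case_ratio_min) || case_ratio_min <= 1) {
    abort("`case_ratio_min` must be a single finite number > 1.")
  }
  if (!is.numeric(control_ratio_max) || length(control_ratio_max) != 1L ||
      !is.finite(control_ratio_max) ||
      control_ratio_max <= 0 || control_ratio_max >= 1) {
    abort("`control_ratio_max` must be a single finite number in (0, 1).")
  }
  structure(
    list(case_ratio_min = case_ratio_min, control_ratio_max = control_ratio_max),
    class = "quant_config"
  )
}

#' @export
print.quant_config <- function(x, ...) {
  cat("<quant_config> enriched in case if ratio >", x$case_ratio_min,
      "| in control if ratio <", x$control_ratio_max, "\n")
  invisible(x)
}
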