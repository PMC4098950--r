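#' Tidy a comparison result
#'
#' Returns the comparison report as a tibble, one row per phosphosite
#' equivalence class (the [comparison_rows()] table).
#'
#' @param x A `"phospho_comparison"` from [run_comparison()].
#' @param ... Unused.
#' @return A tibble of report rows.
#' @method tidy phospho_comparison
#' @export
tidy.phospho_comparison <- function(x, ...) {
  x$rows
}

#' One-row summary of a comparison result
#'
#' @param x A `"phospho_comparison"` from [run_comparison()].
#' @param ... Unused.
#' @return A one-row tibble with the event and protein totals plus the input
#'   PSM counts.
#' @method glance phospho_comparison
#' @export
glance.phospho_comparison <- function(x, ...) {
  bind_cols(x$summary, x$counts, tibble(n_warnings = nrow(x$warnings)))
}

#' Plot a comparison result
#'
#' Two-panel overview: event counts per uniqueness class (case-unique red,
#' control-unique blue, common black, matching the report's color coding)
#' and the modified-residue composition.
#'
#' @param object A `"phospho_comparison"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phospho_comparison
#' @export
autoplot.phospho_comparison <- function(object, ...) {
  status_df <- object$events |>
    count(.data$status) |>
    mutate(status = factor(.data$status,
                           levels = c("unique_case", "common",
                                      "unique_control")))
  ggplot2::ggplot(status_df,
                  ggplot2::aes(x = .data$status, y = .data$n,
                               fill = .data$status)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4,
                       size = 3.2) +
    ggplot2::scale_fill_manual(values = status_colors) +
    ggplot2::labs(x = NULL, y = "modified peptide events",
                  title = "Uniqueness classification") +
    ggplot2::theme_minimal()
}

#' Plot the modified-residue composition
#'
#' @param x A `"phospho_comparison"` or a classified event tibble.
#' @param residues Residues to tally.
#' @return A ggplot object.
#' @export
plot_residue_distribution <- function(x, residues = c("S", "T", "Y", "K")) {
  events <- if (inherits(x, "phospho_comparison")) x$events else x
  frac <- summarize_residue_fractions(events, residues)
  ggplot2::ggplot(frac, ggplot2::aes(x = .data$residue, y = .data$count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percent)),
                       vjust = -0.4, size = 3.2) +
    ggplot2::labs(x = "modified residue", y = "sites",
                  title = "Modified-residue composition") +
    ggplot2::theme_minimal()
}
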