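#' Run the full case-control comparison
#'
#' Orchestrates the whole analysis: parse every PSM export, apply the
#' quality-score filters, discard unmodified peptides, (in quantitative mode)
#' relabel peptides by their abundance ratio, map peptides onto the proteome,
#' group them into phosphosite equivalence classes, classify each event under
#' the multi-engine consensus rule, annotate site novelty, and assemble the
#' report rows. When `output_dir` is given, the HTML report, machine-readable
#' TSV, per-engine statistics files, summary TSV and warning log are written
#' there.
#'
#' @param inputs Tibble (or data frame) with columns `path`, `engine`,
#'   `sample_label` and optionally `file_id`, one row per PSM export file. In
#'   qualitative mode at least one case and one control file are required; in
#'   quantitative mode the files are pooled and labels are taken from the
#'   ratios instead.
#' @param fasta Path to the protein FASTA file, or a ready
#'   [read_fasta()] object.
#' @param known_sites Character vector of known-site database paths, or a
#'   [read_known_sites()] object, or `NULL` (every site reported novel).
#' @param filter A [filter_config()].
#' @param quant A [quant_config()] to run in quantitative mode, or `NULL`
#'   (default) for qualitative mode.
#' @param output_dir Directory for report files, or `NULL` to skip writing.
#' @param log Logical; write the warning log when `output_dir` is given.
#' @param quiet Suppress the printed summary totals.
#' @return An object of class `"phospho_comparison"`: list with `events`
#'   (classified, annotated event tibble), `rows` ([comparison_rows()]
#'   table), `summary` ([comparison_summary()] row), `proteins`
#'   ([unique_phosphoproteins()] table), `partition` ([engine_partition()]),
#'   `warnings` (tibble of `category`, `message` in input order), `filter`,
#'   `quant`, and `counts` (rows parsed/filtered/modified/mapped).
#' @examples
#' \donttest{
#' bundle <- generate_fixtures(fixture_plan(3, 3, 6, n_proteins = 8,
#'                                          seed = 11), tempfile())
#' res <- run_comparison(bundle$files$tables, bundle$files$fasta,
#'                       bundle$files$known_sites, quiet = TRUE)
#' glance(res)
#' }
#' @export
run_comparison <- function(inputs, fasta, known_sites = NULL,
                           filter = filter_config(), quant = NULL,
                           output_dir = NULL, log = TRUE, quiet = FALSE) {
  inputs <- as_tibble(inputs)
  required <- c("path", "engine", "sample_label")
  missing <- setdiff(required, names(inputs))
  if (length(missing) > 0L) {
    abort(sprintf("`inputs` must have columns %s; missing: %s",
                  paste(required, collapse = ", "),
                  paste(missing, collapse = ", ")))
  }
  if (nrow(inputs) == 0L) abort("at least one input file is required")
  if (!"file_id" %in% names(inputs)) inputs$file_id <- basename(inputs$path)
  quant_mode <- !is.null(quant)
  if (quant_mode) stopifnot(inherits(quant, "quant_config"))
  if (!quant_mode) {
    for (lbl in sample_labels) {
      if (!lbl %in% inputs$sample_label) {
        abort(sprintf(
          "a minimum of one case file and one control file is required; no %s file given",
          lbl))
      }
    }
  }

  db <- if (inherits(fasta, "protein_db")) fasta else read_fasta(fasta)
  site_db <- if (is.null(known_sites)) {
    empty_known_sites()
  } else if (inherits(known_sites, "known_site_db")) {
    known_sites
  } else {
    read_known_sites(known_sites)
  }

  warnings <- list()
  note_rejects <- function(rejects, file_id, stage) {
    if (nrow(rejects) > 0L) {
      warnings[[length(warnings) + 1L]] <<- warn_tbl(
        "REJECTED_ROW",
        sprintf("%s: %s row %d: %s", file_id, stage, rejects$row,
                rejects$reason))
    }
  }

  hits <- purrr::pmap(
    inputs[c("path", "engine", "sample_label", "file_id")],
    function(path, engine, sample_label, file_id) {
      h <- tryCatch(
        parse_engine_table(path, engine, sample_label, file_id),
        error = function(e) {
          warnings[[length(warnings) + 1L]] <<- warn_tbl(
            "UNPARSED_FILE", sprintf("%s: %s", path, conditionMessage(e)))
          abort(sprintf("failed to parse input file %s: %s",
                        path, conditionMessage(e)))
        })
      note_rejects(attr(h, "rejects"), file_id, "undecodable")
      h
    }) |> bind_rows()
  n_parsed <- nrow(hits)

  filtered <- apply_filters(hits, filter)
  note_rejects(attr(filtered, "rejects"), "score filter", "missing score in")
  n_filtered <- nrow(filtered)

  modified <- discard_unmodified(filtered, filter)
  n_modified <- nrow(modified)

  if (quant_mode) {
    modified <- apply_quant_mode(modified, quant)
    warnings <- c(warnings, list(attr(modified, "warnings")))
  }

  mapped <- map_hits(modified, db)
  warnings <- c(warnings, list(attr(mapped, "warnings")))

  events <- build_events(mapped)
  warnings <- c(warnings, list(attr(events, "warnings")))
  events <- classify_events(events)
  events <- annotate_events(events, site_db)

  rows <- comparison_rows(events, db)
  summary <- comparison_summary(events)
  warn_tbl_all <- bind_rows(warnings)
  if (nrow(warn_tbl_all) == 0L) warn_tbl_all <- new_warning_tbl()

  result <- structure(
    list(
      events = events,
      rows = rows,
      summary = summary,
      proteins = unique_phosphoproteins(events),
      partition = engine_partition(events),
      warnings = warn_tbl_all,
      filter = filter,
      quant = quant,
      counts = tibble(parsed = n_parsed, filtered = n_filtered,
                      modified = n_modified, mapped = nrow(mapped))
    ),
    class = "phospho_comparison"
  )

  if (!is.null(output_dir)) {
    write_outputs(result, output_dir, log = log, quiet = quiet)
  } else if (!quiet) {
    message(summary_text(summary))
  }
  result
}

#' Write all report files for a comparison
#'
#' @param result A `"phospho_comparison"` from [run_comparison()].
#' @param dir Output directory (created if needed).
#' @param log Write the warning log.
#' @param quiet Suppress printed totals.
#' @return Named character vector of written paths, invisibly.
#' @export
write_outputs <- function(result, dir, log = TRUE, quiet = FALSE) {
  stopifnot(inherits(result, "phospho_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    report_html = file.path(dir, "report.html"),
    report_tsv = file.path(dir, "report.tsv"),
    summary_tsv = file.path(dir, "summary.tsv")
  )
  render_html(result$rows, paths[["report_html"]], events = result$events)
  readr::write_tsv(result$rows, paths[["report_tsv"]], progress = FALSE)
  write_summary(result$summary, paths[["summary_tsv"]], quiet = quiet)
  paths <- c(paths, write_engine_stats(result$events, dir, result$rows))
  if (log) {
    paths <- c(paths, log = write_log(result$warnings,
                                      file.path(dir, "warnings.log")))
  }
  invisible(paths)
}

#' @export
print.phospho_comparison <- function(x, ...) {
  s <- x$summary
  cat("<phospho_comparison>\n")
  cat(sprintf("  mode:     %s\n",
              if (is.null(x$quant)) "qualitative"
              else sprintf("quantitative (> %.3f / < %.3f)",
                           x$quant$case_ratio_min, x$quant$control_ratio_max)))
  cat(sprintf("  inputs:   %d PSM(s) parsed, %d passed filters, %d modified, %d mapped\n",
              x$counts$parsed, x$counts$filtered, x$counts$modified,
              x$counts$mapped))
  cat(sprintf("  events:   %d (%d unique-case, %d unique-control, %d common)\n",
              s$n_events, s$n_unique_case, s$n_unique_control, s$n_common))
  cat(sprintf("  proteins: %d unique in case, %d in control, %d in both sets\n",
              s$n_proteins_case, s$n_proteins_control, s$n_proteins_overlap))
  cat(sprintf("  warnings: %d\n", nrow(x$warnings)))
  invisible(x)
}
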