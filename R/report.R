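mark_sequence <- function(shared_sequence, shared_start, sites, marker = "*") {
  rel <- sort(sites$position[sites$position >= shared_start &
                               sites$position <= shared_start +
                               nchar(shared_sequence) - 1L]) - shared_start + 1L
  if (length(rel) == 0L) return(shared_sequence)
  chars <- strsplit(shared_sequence, "")[[1]]
  chars[rel] <- paste0(chars[rel], marker)
  paste(chars, collapse = "")
}

site_label <- function(sites) {
  paste(sprintf("%s%d", sites$residue, sites$position), collapse = ";")
}

#' Build the comparison report rows
#'
#' Flattens classified, annotated events into one report row per event: the
#' protein accession and description, the shared sequence with modified
#' residues marked by a trailing `*`, the site list with per-site novelty, a
#' detection count per (engine, sample) pair, the uniqueness status, and the
#' modified-residue counts. This table is the machine-readable surface of
#' the report; the HTML output is a styled render of the same rows.
#'
#' @param events Classified and annotated event tibble.
#' @param db Optional [read_fasta()] database to supply protein
#'   descriptions.
#' @param residues Residues tallied into per-row counts.
#' @return A tibble with one row per event, columns `event_id`, `accession`,
#'   `description`, `status`, `shared_sequence`, `marked_sequence`, `sites`,
#'   `novelty`, `known_sources`, `n_<residue>` counts, `det_<engine>_<sample>`
#'   detection counts, `n_members`, `multi_match`, `any_novel`.
#' @export
comparison_rows <- function(events, db = NULL,
                            residues = c("S", "T", "Y", "K")) {
  if (!"status" %in% names(events)) {
    abort("events must be classified (run classify_events()) before reporting")
  }
  desc <- if (!is.null(db)) {
    setNames(db$records$description, db$records$accession)
  } else {
    character()
  }
  base <- tibble(
    event_id = events$event_id,
    accession = events$accession,
    description = unname(desc[events$accession]) %||% NA_character_,
    status = events$status,
    shared_sequence = events$shared_sequence,
    marked_sequence = purrr::pmap_chr(
      list(events$shared_sequence, events$shared_start, events$sites),
      mark_sequence),
    sites = vapply(events$sites, site_label, ""),
    novelty = vapply(events$sites, function(s) {
      if (!"novel" %in% names(s)) return(NA_character_)
      paste(ifelse(s$novel, "novel", "known"), collapse = ";")
    }, ""),
    known_sources = vapply(events$sites, function(s) {
      if (!"known_sources" %in% names(s)) return(NA_character_)
      paste(ifelse(is.na(s$known_sources), "-", s$known_sources),
            collapse = ";")
    }, ""),
    n_members = events$n_members,
    multi_match = events$any_multi,
    any_novel = if ("any_novel" %in% names(events)) events$any_novel else NA
  )
  res_counts <- purrr::map(events$sites, count_modified_residues,
                           residues = residues) |>
    purrr::map(~ as_tibble(as.list(.x))) |>
    bind_rows()
  names(res_counts) <- paste0("n_", residues)

  engines_seen <- sort(unique(unlist(
    purrr::map(events$presence, ~ unique(.x$engine)))))
  det <- purrr::map(events$presence, function(p) {
    grid <- tidyr::expand_grid(engine = engines_seen,
                               sample_label = sample_labels)
    counts <- left_join(grid, p, by = c("engine", "sample_label"))
    counts$n[is.na(counts$n)] <- 0L
    setNames(as.list(counts$n),
             paste0("det_", counts$engine, "_", counts$sample_label)) |>
      as_tibble()
  }) |> bind_rows()

  bind_cols(base, res_counts, det) |>
    arrange(.data$accession, .data$sites)
}

#' Summary totals of a comparison
#'
#' @param events Classified event tibble.
#' @return One-row tibble: event counts per uniqueness class, the event
#'   total, uniquely modified protein counts per sample, and the number of
#'   proteins present in both samples' unique sets (proteins identified in
#'   both samples but with differences in modification sites).
#' @export
comparison_summary <- function(events) {
  prot <- unique_phosphoproteins(events)
  case_prot <- prot$accession[prot$sample_label == "case"]
  control_prot <- prot$accession[prot$sample_label == "control"]
  tibble(
    n_events = nrow(events),
    n_unique_case = sum(events$status == "unique_case"),
    n_unique_control = sum(events$status == "unique_control"),
    n_common = sum(events$status == "common"),
    n_proteins_case = length(case_prot),
    n_proteins_control = length(control_prot),
    n_proteins_overlap = length(intersect(case_prot, control_prot))
  )
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

status_colors <- c(unique_case = "#c0392b", unique_control = "#2c3e9e",
                   common = "#000000")

html_sequence <- function(shared_sequence, shared_start, sites) {
  chars <- strsplit(shared_sequence, "")[[1]]
  rel <- sites$position - shared_start + 1L
  rel <- rel[rel >= 1L & rel <= length(chars)]
  chars[rel] <- paste0("<u>", chars[rel], "</u>")
  paste(chars, collapse = "")
}

html_sites <- function(sites) {
  labels <- sprintf("%s%d", sites$residue, sites$position)
  if ("novel" %in% names(sites)) {
    labels <- ifelse(sites$novel, paste0("<b>", labels, "</b>"), labels)
  }
  paste(labels, collapse = "; ")
}

#' Render the HTML comparison report
#'
#' Writes a single self-contained HTML file. Rows unique to the case sample
#' are styled red, unique to the control sample blue, and common rows black;
#' modified residues are underlined in the shared sequence and novel sites
#' are bold. Every styled fact is also present in machine-readable `data-*`
#' attributes (`data-status`, `data-accession`, `data-sites`, `data-novelty`,
#' ...), so consumers never need to interpret the styling.
#'
#' @param rows Report rows from [comparison_rows()].
#' @param path Output file path.
#' @param events The event tibble the rows came from (site-level detail for
#'   underlining/bolding); optional — without it the marked text falls back
#'   to the `marked_sequence` column.
#' @param title Report title.
#' @return `path`, invisibly.
#' @export
render_html <- function(rows, path, events = NULL,
                        title = "Modified-peptide comparison report") {
  counts <- c(
    unique_case = sum(rows$status == "unique_case"),
    unique_control = sum(rows$status == "unique_control"),
    common = sum(rows$status == "common")
  )
  ev_lookup <- if (!is.null(events)) {
    setNames(seq_len(nrow(events)), events$event_id)
  }
  data_cols <- setdiff(names(rows), character())
  body_rows <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    seq_html <- if (!is.null(ev_lookup) && r$event_id %in% names(ev_lookup)) {
      e <- events[ev_lookup[[r$event_id]], ]
      html_sequence(e$shared_sequence, e$shared_start, e$sites[[1]])
    } else {
      html_escape(r$marked_sequence)
    }
    sites_html <- if (!is.null(ev_lookup) && r$event_id %in% names(ev_lookup)) {
      html_sites(events$sites[[ev_lookup[[r$event_id]]]])
    } else {
      html_escape(r$sites)
    }
    attrs <- paste(sprintf('data-%s="%s"',
                           gsub("_", "-", data_cols),
                           html_escape(vapply(data_cols, function(cn)
                             paste(format(r[[cn]], trim = TRUE), collapse = ""),
                             ""))),
                   collapse = " ")
    det_cols <- grep("^det_", data_cols, value = TRUE)
    det_cells <- paste(sprintf("<td>%s</td>",
                               vapply(det_cols, function(cn)
                                 as.character(r[[cn]]), "")),
                       collapse = "")
    sprintf(
      '<tr class="%s" %s><td>%s</td><td>%s</td><td>%s</td><td>%s</td>%s<td>%s</td><td>%d</td><td>%d</td><td>%d</td><td>%d</td></tr>',
      r$status, attrs, html_escape(r$accession),
      html_escape(ifelse(is.na(r$description), "", r$description)),
      seq_html, sites_html, det_cells, r$status,
      r$n_S %||% 0L, r$n_T %||% 0L, r$n_Y %||% 0L, r$n_K %||% 0L
    )
  }, "")
  det_cols <- grep("^det_", names(rows), value = TRUE)
  header <- paste(sprintf("<th>%s</th>", c(
    "Accession", "Protein name / description",
    "Shared sequence (modified residues underlined)",
    "Sites (novel in bold)", gsub("^det_", "", det_cols),
    "Status", "S", "T", "Y", "K"
  )), collapse = "")
  doc <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    sprintf("<title>%s</title>", html_escape(title)),
    "<style>",
    "body { font-family: sans-serif; }",
    "table { border-collapse: collapse; }",
    "td, th { border: 1px solid #ccc; padding: 2px 6px; font-size: 90%; }",
    sprintf("tr.unique_case td { color: %s; }", status_colors[["unique_case"]]),
    sprintf("tr.unique_control td { color: %s; }",
            status_colors[["unique_control"]]),
    sprintf("tr.common td { color: %s; }", status_colors[["common"]]),
    "</style></head><body>",
    sprintf("<h1>%s</h1>", html_escape(title)),
    sprintf(paste0(
      '<p id="summary" data-n-unique-case="%d" data-n-unique-control="%d" ',
      'data-n-common="%d">%d peptide(s) unique to case, %d unique to control, ',
      "%d common to both samples.</p>"),
      counts[["unique_case"]], counts[["unique_control"]], counts[["common"]],
      counts[["unique_case"]], counts[["unique_control"]], counts[["common"]]),
    "<table><thead><tr>", header, "</tr></thead><tbody>",
    body_rows,
    "</tbody></table></body></html>"
  )
  writeLines(doc, path)
  invisible(path)
}

#' Write per-engine statistics files
#'
#' For every search engine two TSV files are written into `dir`:
#' `<engine>_peptides.tsv`, listing every modified peptide event that engine
#' identified, and `<engine>_unique_proteins.tsv`, listing the uniquely
#' modified proteins attributable from that engine's detections (events with
#' a unique status, all members unambiguously mapped).
#'
#' @param events Classified event tibble.
#' @param dir Output directory (created if needed).
#' @param rows Optional precomputed [comparison_rows()] to draw peptide rows
#'   from.
#' @return Named character vector of written paths, invisibly.
#' @export
write_engine_stats <- function(events, dir, rows = comparison_rows(events)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  part <- engine_partition(events)
  paths <- character()
  for (i in seq_len(nrow(part))) {
    eng <- part$engine[i]
    detected <- part$detected[[i]]
    pep_path <- file.path(dir, paste0(eng, "_peptides.tsv"))
    pep_rows <- rows[rows$event_id %in% detected, , drop = FALSE] |>
      select("event_id", "accession", "status", "shared_sequence", "sites",
             "n_members")
    readr::write_tsv(pep_rows, pep_path, progress = FALSE)

    uniq <- events[events$event_id %in% detected & !events$any_multi &
                     events$status %in% c("unique_case", "unique_control"), ,
                   drop = FALSE]
    prot <- tibble(
      sample_label = ifelse(uniq$status == "unique_case", "case", "control"),
      accession = uniq$accession
    ) |> distinct() |> arrange(.data$sample_label, .data$accession)
    prot_path <- file.path(dir, paste0(eng, "_unique_proteins.tsv"))
    readr::write_tsv(prot, prot_path, progress = FALSE)
    paths <- c(paths, setNames(c(pep_path, prot_path),
                               paste0(eng, c("_peptides", "_unique_proteins"))))
  }
  invisible(paths)
}

#' Write the warning log
#'
#' One line per warning, `CATEGORY<TAB>message`, in the order the warnings
#' arose. An empty log file is still created so a clean run is
#' distinguishable from logging being disabled.
#'
#' @param warnings Tibble with `category` and `message` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_log <- function(warnings, path) {
  lines <- if (nrow(warnings) > 0L) {
    sprintf("%s\t%s", warnings$category, warnings$message)
  } else {
    character()
  }
  writeLines(lines, path)
  invisible(path)
}

summary_text <- function(summary) {
  sprintf(
    "%d unique-case, %d unique-control and %d common modified peptide(s); %d / %d uniquely modified protein(s) (case/control), %d protein(s) in both unique sets",
    summary$n_unique_case, summary$n_unique_control, summary$n_common,
    summary$n_proteins_case, summary$n_proteins_control,
    summary$n_proteins_overlap)
}

#' Write the summary TSV
#'
#' @param summary One-row summary from [comparison_summary()].
#' @param path Output path.
#' @param quiet Suppress printing the totals to the console.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, quiet = FALSE) {
  long <- tibble(metric = names(summary),
                 value = as.integer(unlist(summary[1, ])))
  readr::write_tsv(long, path, progress = FALSE)
  if (!quiet) message(summary_text(summary))
  invisible(path)
}
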