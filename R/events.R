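site_key <- function(sites) {
  s <- dplyr::arrange(sites, .data$position, .data$residue, .data$mod_type)
  paste(sprintf("%s%d/%s", s$residue, s$position, s$mod_type), collapse = ";")
}

#' Group mapped peptides into phosphosite equivalence classes
#'
#' The unit of comparison is not the peptide sequence but the *event*: all
#' reported peptides on one protein whose modified-site sets are identical,
#' regardless of peptide length (two peptides of different lengths carrying
#' the same phosphosite are the same event and count as two members). Each
#' event's representative sequence is the shared sequence — the intersection
#' of the member peptides' protein intervals, which always contains every
#' site. Should the intersection ever come out empty (impossible when every
#' member covers its own sites, but guarded against), the minimal interval
#' covering all site positions is used and an `EMPTY_INTERSECTION` warning
#' emitted.
#'
#' @param mapped Mapped hit tibble from [map_hits()].
#' @return An event tibble, one row per (accession, site set): `event_id`,
#'   `accession`, `site_key`, `sites` (tibble of `position`, `residue`,
#'   `mod_type`), `n_members`, `shared_start`, `shared_end`,
#'   `shared_sequence`, `any_multi` (any member was a multi-match),
#'   `presence` (tibble of `engine`, `sample_label`, `n` detections), and
#'   `members` (tibble of member hits). Attribute `"warnings"`.
#' @export
build_events <- function(mapped) {
  if (nrow(mapped) == 0L) {
    out <- tibble(
      event_id = character(), accession = character(), site_key = character(),
      sites = list(), n_members = integer(), shared_start = integer(),
      shared_end = integer(), shared_sequence = character(),
      any_multi = logical(), presence = list(), members = list()
    )
    attr(out, "warnings") <- new_warning_tbl()
    return(out)
  }
  mapped$site_key <- vapply(mapped$sites, site_key, "")
  warnings <- list()

  grouped <- mapped |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$accession, .data$site_key)
  keys <- dplyr::group_keys(grouped)
  rows <- dplyr::group_rows(grouped)

  events <- purrr::map2(seq_len(nrow(keys)), rows, function(k, idx) {
    mem <- mapped[idx, , drop = FALSE]
    sites <- mem$sites[[1]]
    s0 <- max(mem$start)
    e0 <- min(mem$end)
    if (s0 > e0) {
      warnings[[length(warnings) + 1L]] <<- warn_tbl(
        "EMPTY_INTERSECTION", sprintf(
          "event %s|%s: member intervals do not overlap; using minimal site-covering interval",
          keys$accession[k], keys$site_key[k]))
      s0 <- min(sites$position)
      e0 <- max(sites$position)
    }
    ref <- which.max(mem$start <= s0 & mem$end >= e0)
    shared_seq <- substr(mem$peptide[ref], s0 - mem$start[ref] + 1L,
                         e0 - mem$start[ref] + 1L)
    presence <- mem |>
      count(.data$engine, .data$sample_label, name = "n") |>
      arrange(.data$engine, .data$sample_label)
    tibble(
      event_id = paste(keys$accession[k], keys$site_key[k], sep = "|"),
      accession = keys$accession[k],
      site_key = keys$site_key[k],
      sites = list(sites),
      n_members = nrow(mem),
      shared_start = as.integer(s0),
      shared_end = as.integer(e0),
      shared_sequence = shared_seq,
      any_multi = any(mem$multi_match),
      presence = list(presence),
      members = list(select(mem, "engine", "sample_label", "file_id",
                            "peptide", "start", "end", "multi_match", "ratio"))
    )
  }) |> bind_rows() |>
    arrange(.data$accession, .data$shared_start, .data$site_key)

  w <- bind_rows(warnings)
  if (nrow(w) == 0L) w <- new_warning_tbl()
  attr(events, "warnings") <- w
  events
}

#' Classify an event's uniqueness under the multi-engine consensus rule
#'
#' An event is uniquely modified in the case sample only if it was detected
#' in the case sample by at least one search engine and not detected in the
#' control sample by any engine; symmetrically for the control sample; every
#' other detection pattern is common to both samples.
#'
#' @param presence A tibble with columns `engine`, `sample_label`, `n`
#'   (detection counts), as stored in an event's `presence` field.
#' @return One of `"unique_case"`, `"unique_control"`, `"common"`.
#' @examples
#' classify_uniqueness(tibble::tibble(
#'   engine = c("mascot", "paragon"),
#'   sample_label = c("case", "case"), n = c(1, 2)
#' ))
#' @export
classify_uniqueness <- function(presence) {
  case_n <- sum(presence$n[presence$sample_label == "case"])
  control_n <- sum(presence$n[presence$sample_label == "control"])
  if (case_n + control_n == 0) {
    abort("ill-formed event: no detections in any engine or sample")
  }
  if (case_n >= 1 && control_n == 0) return("unique_case")
  if (control_n >= 1 && case_n == 0) return("unique_control")
  "common"
}

#' Assign a uniqueness status to every event
#'
#' @param events Event tibble from [build_events()].
#' @return `events` with an added `status` column; exactly one status per
#'   event, so the unique-case, unique-control and common counts always
#'   partition the event total.
#' @export
classify_events <- function(events) {
  events$status <- vapply(events$presence, classify_uniqueness, "")
  events
}

#' Uniquely modified proteins per sample
#'
#' A protein is uniquely modified in a sample if it owns at least one event
#' with the matching unique status all of whose member peptides mapped
#' unambiguously (no multi-match member) to that protein.
#'
#' @param events Classified event tibble.
#' @return Tibble with columns `sample_label` and `accession`, one row per
#'   (sample, protein), sorted.
#' @export
unique_phosphoproteins <- function(events) {
  eligible <- events[!events$any_multi &
                       events$status %in% c("unique_case", "unique_control"), ,
                     drop = FALSE]
  tibble(
    sample_label = ifelse(eligible$status == "unique_case", "case", "control"),
    accession = eligible$accession
  ) |>
    distinct() |>
    arrange(.data$sample_label, .data$accession)
}

#' Partition events by detecting search engine
#'
#' For every engine, lists the events that engine detected and the events
#' only that engine detected (supporting vs complementary evidence between
#' engines). The "only" sets are pairwise disjoint by construction.
#'
#' @param events Event tibble (classified or not).
#' @return Tibble with columns `engine`, `detected` (list of event_id
#'   vectors), `exclusive` (list of event_id vectors).
#' @export
engine_partition <- function(events) {
  long <- purrr::map2(events$event_id, events$presence, function(id, p) {
    det <- unique(p$engine[p$n > 0])
    tibble(event_id = id, engine = det, n_engines = length(det))
  }) |> bind_rows()
  if (nrow(long) == 0L) {
    return(tibble(engine = character(), detected = list(), exclusive = list()))
  }
  long |>
    group_by(.data$engine) |>
    summarise(
      detected = list(.data$event_id),
      exclusive = list(.data$event_id[.data$n_engines == 1L]),
      .groups = "drop"
    ) |>
    arrange(.data$engine)
}
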