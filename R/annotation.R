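#' Annotate site novelty against known-site databases
#'
#' A site is *known* if the exact tuple (accession, position, residue,
#' modification type) appears in the union of the loaded databases, and
#' *novel* otherwise. Matching is exact and residue-checked: a database entry
#' for serine at a position never validates an observed threonine there, which
#' guards against coordinate drift between FASTA versions. An optional
#' positional tolerance is provided as a configuration hook for databases
#' built on slightly different sequence versions; it is off by default.
#'
#' @param sites Tibble with columns `accession`, `position`, `residue`,
#'   `mod_type`.
#' @param db A [read_known_sites()] database (possibly empty, in which case
#'   every site is novel).
#' @param position_tolerance Non-negative integer; a database entry within
#'   this many residues (same accession, residue and type) counts as a match.
#'   Default 0 (exact).
#' @return `sites` with added columns `novel` (logical) and `known_sources`
#'   (comma-separated database names, `NA` for novel sites).
#' @export
annotate_novelty <- function(sites, db = empty_known_sites(),
                             position_tolerance = 0L) {
  sites <- as_tibble(sites)
  if (nrow(sites) == 0L) {
    sites$novel <- logical()
    sites$known_sources <- character()
    return(sites)
  }
  if (position_tolerance == 0L) {
    matched <- left_join(
      sites, as_tibble(db),
      by = c("accession", "position", "residue", "mod_type")
    )
    sites$known_sources <- matched$sources
  } else {
    sites$known_sources <- purrr::pmap_chr(
      sites[c("accession", "position", "residue", "mod_type")],
      function(accession, position, residue, mod_type) {
        hit <- db$sources[db$accession == accession &
                            db$residue == residue &
                            db$mod_type == mod_type &
                            abs(db$position - position) <= position_tolerance]
        if (length(hit) == 0L) NA_character_ else
          paste(sort(unique(unlist(strsplit(hit, ",")))), collapse = ",")
      }
    )
  }
  sites$novel <- is.na(sites$known_sources)
  sites
}

#' Annotate every event's sites for novelty
#'
#' @param events Event tibble from [build_events()].
#' @inheritParams annotate_novelty
#' @return `events` with the per-event `sites` tibbles gaining `novel` and
#'   `known_sources` columns, plus an event-level `any_novel` flag.
#' @export
annotate_events <- function(events, db = empty_known_sites(),
                            position_tolerance = 0L) {
  events$sites <- purrr::map2(events$sites, events$accession, function(s, acc) {
    s$accession <- acc
    out <- annotate_novelty(s, db, position_tolerance)
    out[setdiff(names(out), "accession")]
  })
  events$any_novel <- vapply(events$sites, function(s) any(s$novel), TRUE)
  events
}

#' Count modified residues in an event
#'
#' @param sites An event's site tibble (columns `residue` at minimum), or an
#'   event row's `sites[[1]]`.
#' @param residues Residue letters to report; absent residues report 0.
#' @return Named integer vector of counts per residue.
#' @examples
#' count_modified_residues(tibble::tibble(
#'   position = c(3, 6, 7), residue = c("S", "S", "T"),
#'   mod_type = "phospho"
#' ))
#' @export
count_modified_residues <- function(sites, residues = c("S", "T", "Y", "K")) {
  counts <- table(factor(sites$residue, levels = residues))
  setNames(as.integer(counts), residues)
}

#' Residue composition of all modified sites
#'
#' Tallies modified residues across non-redundant events (each event's site
#' set counted once) and expresses each residue as a percentage of all
#' modified residues, rounded to one decimal as in the report. Accepts either
#' a classified event tibble or a pre-computed named count vector, so the
#' summary can be recomputed from published count tables directly.
#'
#' @param events Event tibble, or a named numeric vector of residue counts.
#' @param residues Residue letters to report.
#' @return Tibble with columns `residue`, `count`, `percent` (one-decimal).
#'   With zero sites all percents are 0 (no division error).
#' @examples
#' summarize_residue_fractions(c(S = 2532, T = 418, Y = 15, K = 8))
#' @export
summarize_residue_fractions <- function(events,
                                        residues = c("S", "T", "Y", "K")) {
  counts <- if (is.numeric(events)) {
    vapply(residues, function(r) {
      if (r %in% names(events)) as.numeric(events[[r]]) else 0
    }, 1)
  } else {
    all_sites <- bind_rows(events$sites)
    if (nrow(all_sites) == 0L) {
      setNames(rep(0, length(residues)), residues)
    } else {
      as.numeric(count_modified_residues(all_sites, residues))
    }
  }
  total <- sum(counts)
  percent <- if (total > 0) round(100 * counts / total, 1) else counts * 0
  tibble(residue = residues, count = unname(counts), percent = unname(percent))
}
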