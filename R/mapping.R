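#' Locate a peptide within a protein sequence
#'
#' Exact substring search returning every 1-based start position, including
#' overlapping occurrences, in ascending order.
#'
#' @param peptide Uppercase peptide sequence.
#' @param protein Uppercase protein sequence.
#' @return Integer vector of start positions (possibly empty).
#' @examples
#' locate_peptide("SAPSTR", "MKSAPSTR") # 3
#' locate_peptide("AA", "AAAA")         # 1 2 3
#' @export
locate_peptide <- function(peptide, protein) {
  stopifnot(nzchar(peptide), nzchar(protein))
  if (nchar(peptide) > nchar(protein)) return(integer())
  m <- Biostrings::matchPattern(peptide, Biostrings::AAString(protein))
  sort(Biostrings::start(m))
}

# one whole-database scan per distinct peptide; returns tibble(accession, start)
locate_in_db <- function(peptide, db) {
  hits <- Biostrings::vmatchPattern(peptide, db$aa)
  starts <- Biostrings::startIndex(hits)
  n <- lengths(starts)
  found <- which(n > 0L)
  tibble(
    accession = rep(names(db$aa)[found], n[found]),
    start = unlist(starts[found], use.names = FALSE) %||% integer()
  )
}

#' Map hits onto protein coordinates
#'
#' Each hit's peptide is located in the proteome and its peptide-relative
#' modification positions are translated to absolute protein positions
#' (`protein_position = start + peptide_position - 1`, 1-based inclusive
#' coordinates throughout). The primary protein is the first engine-reported
#' accession that is present in the database and contains the peptide; if no
#' reported accession resolves, a whole-database scan rescues the hit (with
#' an `ACCESSION_MISMATCH` warning) rather than losing it silently. A peptide
#' occurring in more than one protein, or at more than one position within
#' its protein, is mapped to the lowest position of the primary protein but
#' flagged `multi_match` (with a `MULTI_MATCH` warning); such peptides are
#' later excluded from unique-protein attribution. Peptides found nowhere are
#' returned in the `"unmapped"` attribute with an `UNMAPPED_PEPTIDE` warning.
#'
#' @param hits Hit tibble from [parse_engine_table()] pipeline steps.
#' @param db A [read_fasta()] protein database.
#' @return Tibble of mapped hits: the input columns plus `accession`,
#'   `start`, `end`, `multi_match`, and `sites` (list of tibbles with
#'   `position`, `residue`, `mod_type`, sorted by position). Attributes:
#'   `"unmapped"` (tibble of unmapped hits) and `"warnings"` (tibble of
#'   `category`, `message`).
#' @export
map_hits <- function(hits, db) {
  stopifnot(inherits(db, "protein_db"))
  peptides <- unique(hits$peptide)
  lookup <- setNames(lapply(peptides, locate_in_db, db = db), peptides)

  n <- nrow(hits)
  accession <- character(n)
  start <- integer(n)
  multi <- logical(n)
  mapped <- logical(n)
  warnings <- vector("list", n)

  for (i in seq_len(n)) {
    loc <- lookup[[hits$peptide[i]]]
    if (nrow(loc) == 0L) {
      warnings[[i]] <- warn_tbl("UNMAPPED_PEPTIDE", sprintf(
        "peptide %s (%s, %s) not found in the protein database",
        hits$peptide[i], hits$engine[i], hits$file_id[i]))
      next
    }
    reported <- hits$accessions[[i]]
    primary <- reported[reported %in% loc$accession][1]
    if (is.na(primary)) {
      primary <- loc$accession[1]
      warnings[[i]] <- warn_tbl("ACCESSION_MISMATCH", sprintf(
        "peptide %s: reported accession(s) %s absent from database; mapped to %s by sequence scan",
        hits$peptide[i], paste(reported, collapse = ";"), primary))
    }
    in_primary <- loc$start[loc$accession == primary]
    accession[i] <- primary
    start[i] <- min(in_primary)
    multi[i] <- length(unique(loc$accession)) > 1L || length(in_primary) > 1L
    mapped[i] <- TRUE
    if (multi[i]) {
      warnings[[i]] <- bind_rows(warnings[[i]], warn_tbl("MULTI_MATCH", sprintf(
        "peptide %s matches %d position(s) across protein(s) %s",
        hits$peptide[i], nrow(loc),
        paste(unique(loc$accession), collapse = ";"))))
    }
  }

  out <- hits[mapped, , drop = FALSE]
  out$accession <- accession[mapped]
  out$start <- start[mapped]
  out$end <- out$start + nchar(out$peptide) - 1L
  out$multi_match <- multi[mapped]
  out$sites <- purrr::map2(out$mods, out$start, function(m, s) {
    tibble(position = m$pos + s - 1L, residue = m$residue,
           mod_type = m$mod_type) |>
      arrange(.data$position, .data$residue, .data$mod_type)
  })
  attr(out, "unmapped") <- hits[!mapped, , drop = FALSE]
  w <- bind_rows(warnings)
  if (nrow(w) == 0L) w <- new_warning_tbl()
  attr(out, "warnings") <- w
  out
}
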