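#' Read a protein FASTA file
#'
#' Loads a proteome and extracts accessions according to the header dialect:
#' UniProt (`>sp|P12345|NAME_HUMAN description` or `tr|...`, accession is the
#' second pipe field) or RefSeq (`>ref|NP_000001.1|` or a bare
#' `>NP_000001.1 description`, accession is the `ref|` field or the first
#' whitespace-delimited token). The dialect is auto-detected from the first
#' header and can be forced.
#'
#' @param path Path to a FASTA file.
#' @param dialect `"auto"` (default), `"uniprot"`, or `"refseq"`.
#' @return An object of class `"protein_db"`: list with `records` (tibble of
#'   `accession`, `sequence`, `description`), `dialect`, and `aa` (a named
#'   [Biostrings::AAStringSet] used for fast peptide location).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P12345|TEST_HUMAN demo protein", "MKSAPSTR"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, dialect = c("auto", "uniprot", "refseq")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("FASTA file does not exist: %s", path))
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) abort(sprintf(
                   "cannot read FASTA %s: %s", path, conditionMessage(e))))
  if (length(aa) == 0L) abort(sprintf("FASTA file %s contains no records", path))

  headers <- names(aa)
  if (dialect == "auto") {
    dialect <- if (grepl("^(sp|tr)\\|", headers[1])) "uniprot" else "refseq"
  }
  first_token <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  accession <- if (dialect == "uniprot") {
    vapply(strsplit(first_token, "|", fixed = TRUE), function(p) {
      if (length(p) >= 2L) p[2] else p[1]
    }, "")
  } else {
    ifelse(grepl("ref\\|", first_token),
           sub("^.*ref\\|([^|]+)\\|?.*$", "\\1", first_token),
           first_token)
  }
  dup <- accession[duplicated(accession)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicate accession(s) in %s: %s",
                  path, paste(unique(dup), collapse = ", ")))
  }
  sequences <- toupper(as.character(aa))
  if (any(!nzchar(sequences))) abort(sprintf("empty sequence in %s", path))
  aa <- Biostrings::AAStringSet(sequences)
  names(aa) <- accession
  structure(
    list(
      records = tibble(accession = accession, sequence = unname(sequences),
                       description = description),
      dialect = dialect,
      aa = aa
    ),
    class = "protein_db"
  )
}

#' @export
print.protein_db <- function(x, ...) {
  cat(sprintf("<protein_db> %d protein(s), %s headers\n",
              nrow(x$records), x$dialect))
  print(head(x$records, 5))
  invisible(x)
}

#' Write a protein database to FASTA
#'
#' Inverse of [read_fasta()], used by the fixture generator.
#'
#' @param db A `"protein_db"` or a tibble with `accession`, `sequence`,
#'   `description` columns.
#' @param path Output path.
#' @param dialect Header dialect to emit.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, dialect = c("uniprot", "refseq")) {
  dialect <- match.arg(dialect)
  rec <- if (inherits(db, "protein_db")) db$records else as_tibble(db)
  header <- if (dialect == "uniprot") {
    sprintf("sp|%s|%s_SYN %s", rec$accession, rec$accession, rec$description)
  } else {
    sprintf("%s %s", rec$accession, rec$description)
  }
  writeLines(paste0(">", trimws(header), "\n", rec$sequence), path)
  invisible(path)
}

#' Read known modification-site databases
#'
#' Loads one or more flat-file site databases (UniProt / PHOSIDA /
#' PhosphoSitePlus-style exports reduced to four tab-separated columns:
#' accession, 1-based protein position, residue letter, modification type).
#' Files may or may not carry a header row. The databases are unioned;
#' duplicate sites collapse to one entry whose `sources` field lists every
#' database that reported it, so load order never changes an annotation.
#' Malformed rows are rejected row-wise and surfaced via the `"rejects"`
#' attribute.
#'
#' @param paths Character vector of file paths.
#' @param sources Names for the databases (provenance in reports); defaults
#'   to the file names without extension.
#' @return A tibble of class `"known_site_db"` with columns `accession`,
#'   `position`, `residue`, `mod_type`, `sources`.
#' @export
read_known_sites <- function(paths, sources = NULL) {
  if (is.null(sources)) {
    sources <- sub("\\.[^.]*$", "", basename(paths))
  }
  stopifnot(length(sources) == length(paths))
  rejects <- new_warning_tbl()
  all <- purrr::map2(paths, sources, function(path, src) {
    if (!file.exists(path)) abort(sprintf("site database not found: %s", path))
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) > 0L && grepl("^accession\\b", lines[1], ignore.case = TRUE)) {
      lines <- lines[-1]
    }
    if (length(lines) == 0L) {
      return(tibble(accession = character(), position = integer(),
                    residue = character(), mod_type = character(),
                    source = character()))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok <- vapply(fields, function(f) {
      length(f) >= 4L && !is.na(suppressWarnings(as.integer(f[2]))) &&
        as.integer(f[2]) >= 1L && grepl("^[A-Za-z]$", trimws(f[3])) &&
        tolower(trimws(f[4])) %in% c("phospho", "acetyl")
    }, TRUE)
    if (any(!ok)) {
      rejects <<- bind_rows(rejects, warn_tbl(
        "REJECTED_ROW",
        sprintf("%s: malformed site row %d: '%s'", basename(path),
                which(!ok), lines[!ok])
      ))
    }
    fields <- fields[ok]
    tibble(
      accession = vapply(fields, function(f) trimws(f[1]), ""),
      position = vapply(fields, function(f) as.integer(f[2]), 1L),
      residue = toupper(vapply(fields, function(f) trimws(f[3]), "")),
      mod_type = tolower(vapply(fields, function(f) trimws(f[4]), "")),
      source = src
    )
  })
  db <- bind_rows(all) |>
    distinct(.data$accession, .data$position, .data$residue, .data$mod_type,
             .data$source) |>
    group_by(.data$accession, .data$position, .data$residue, .data$mod_type) |>
    summarise(sources = paste(sort(unique(.data$source)), collapse = ","),
              .groups = "drop") |>
    arrange(.data$accession, .data$position, .data$residue, .data$mod_type)
  class(db) <- c("known_site_db", class(db))
  attr(db, "rejects") <- rejects
  db
}

#' An empty known-site database
#'
#' Convenience constructor for runs without literature annotation; every
#' observed site is then reported as novel.
#' @return An empty `"known_site_db"` tibble.
#' @export
empty_known_sites <- function() {
  db <- tibble(accession = character(), position = integer(),
               residue = character(), mod_type = character(),
               sources = character())
  class(db) <- c("known_site_db", class(db))
  db
}
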