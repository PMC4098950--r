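#' @title Engine export dialects
#' @description
#' Vendor PSM exports vary by software version, so the package defines one
#' frozen canonical layout per engine (a column-mapping hook for real-world
#' exports is `col_map` in [parse_engine_table()]):
#'
#' * **mascot** — CSV. Columns `prot_acc` (semicolon-separated accessions),
#'   `pep_seq`, `pep_score` (ion score), `pep_expect`, `pep_var_mod_pos`;
#'   optional `pep_loc_score`, `pep_ratio`. The modification string follows
#'   the Mascot positional convention `"0.XXX...X.0"`: one digit per peptide
#'   residue between the two dots, `0` unmodified, `1` phospho, `2` acetyl.
#' * **paragon** — TSV. Columns `Accessions`, `Sequence`, `Conf` (peptide
#'   confidence, percent), `Modifications`; optional `LocScore`, `Ratio`.
#'   Modifications are `;`-separated tokens `Type(Residue)@Position`, e.g.
#'   `"Phospho(S)@3; Acetyl(K)@7"`.
#' * **sequest_pd** — TSV (Proteome Discoverer PSM export). Columns
#'   `Protein Group Accessions`, `Sequence`, `Modifications`; optional
#'   `XCorr`, `LocScore`, `Ratio`. Modifications are `;`-separated tokens
#'   `ResiduePosition(Type)`, e.g. `"S3(Phospho); K7(Acetyl)"`.
#'
#' All dialects share the semantics: positions are 1-based within the peptide
#' and the named residue must match the peptide sequence at that position.
#' @name engine_dialects
NULL

engines <- c("mascot", "paragon", "sequest_pd")
sample_labels <- c("case", "control")
mod_digit <- c(phospho = "1", acetyl = "2")

empty_mods <- function() {
  tibble(pos = integer(), residue = character(), mod_type = character())
}

required_cols <- list(
  mascot = c("prot_acc", "pep_seq", "pep_expect", "pep_var_mod_pos"),
  paragon = c("Accessions", "Sequence", "Conf", "Modifications"),
  sequest_pd = c("Protein Group Accessions", "Sequence", "Modifications")
)

# ---- modification-string grammars -----------------------------------------

parse_mods_mascot <- function(str, peptide) {
  if (is.na(str) || !nzchar(str)) return(empty_mods())
  parts <- strsplit(str, ".", fixed = TRUE)[[1]]
  if (length(parts) != 3L || nchar(parts[2]) != nchar(peptide)) {
    return(sprintf("modification string '%s' does not align with peptide", str))
  }
  digits <- strsplit(parts[2], "")[[1]]
  if (!all(digits %in% c("0", mod_digit))) {
    return(sprintf("unknown modification key in '%s'", str))
  }
  idx <- which(digits != "0")
  if (length(idx) == 0L) return(empty_mods())
  tibble(
    pos = idx,
    residue = substring(peptide, idx, idx),
    mod_type = names(mod_digit)[match(digits[idx], mod_digit)]
  )
}

parse_mod_tokens <- function(str, peptide, pattern, fields) {
  if (is.na(str) || !nzchar(trimws(str))) return(empty_mods())
  tokens <- trimws(strsplit(str, ";", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  m <- regmatches(tokens, regexec(pattern, tokens))
  if (any(lengths(m) == 0L)) {
    return(sprintf("undecodable modification token in '%s'", str))
  }
  mods <- tibble(
    pos = as.integer(vapply(m, `[`, "", fields["pos"] + 1L)),
    residue = vapply(m, `[`, "", fields["residue"] + 1L),
    mod_type = tolower(vapply(m, `[`, "", fields["type"] + 1L))
  )
  bad <- mods$pos < 1L | mods$pos > nchar(peptide) |
    substring(peptide, mods$pos, mods$pos) != mods$residue
  if (any(bad)) {
    return(sprintf("modification position/residue mismatch in '%s'", str))
  }
  mods
}

parse_mods_paragon <- function(str, peptide) {
  parse_mod_tokens(str, peptide,
                   "^(Phospho|Acetyl)\\(([A-Z])\\)@([0-9]+)$",
                   c(type = 1L, residue = 2L, pos = 3L))
}

parse_mods_sequest <- function(str, peptide) {
  parse_mod_tokens(str, peptide,
                   "^([A-Z])([0-9]+)\\((Phospho|Acetyl)\\)$",
                   c(residue = 1L, pos = 2L, type = 3L))
}

format_mods <- function(mods, peptide, engine) {
  if (nrow(mods) == 0L) {
    return(if (engine == "mascot") {
      paste0("0.", strrep("0", nchar(peptide)), ".0")
    } else "")
  }
  mods <- dplyr::arrange(mods, .data$pos)
  switch(engine,
    mascot = {
      digits <- rep("0", nchar(peptide))
      digits[mods$pos] <- mod_digit[mods$mod_type]
      paste0("0.", paste(digits, collapse = ""), ".0")
    },
    paragon = paste(
      sprintf("%s(%s)@%d", tools::toTitleCase(mods$mod_type),
              mods$residue, mods$pos),
      collapse = "; "
    ),
    sequest_pd = paste(
      sprintf("%s%d(%s)", mods$residue, mods$pos,
              tools::toTitleCase(mods$mod_type)),
      collapse = "; "
    )
  )
}

# ---- parsing ---------------------------------------------------------------

#' Parse a search-engine PSM export table
#'
#' Reads one exported peptide-spectrum-match table in the engine's canonical
#' dialect (see [engine_dialects]) and decodes each row into a hit with
#' residue-level modification assignments. Rows whose modification string
#' cannot be decoded, or that lack a peptide sequence, are not fatal: they are
#' collected in the `rejects` attribute (one row, one reason) so that
#' `nrow(parsed) + nrow(rejects)` always equals the number of data rows.
#'
#' @param path Path to the CSV (mascot) or TSV (paragon, sequest_pd) export.
#' @param engine One of `"mascot"`, `"paragon"`, `"sequest_pd"`.
#' @param sample_label `"case"` or `"control"`.
#' @param file_id Identifier kept with every hit for provenance; defaults to
#'   the file name.
#' @param col_map Optional named character vector renaming real-world export
#'   columns onto the canonical ones, e.g.
#'   `c(pep_seq = "Peptide sequence")`.
#' @return A tibble of hits with columns `engine`, `sample_label`, `file_id`,
#'   `peptide`, `accessions` (list of character), `mods` (list of tibbles
#'   with `pos`, `residue`, `mod_type`), and numeric score columns `expect`,
#'   `ion_score`, `xcorr`, `confidence`, `loc_score`, `ratio` (`NA` where the
#'   engine does not report them). Attribute `"rejects"`: tibble with `row`
#'   and `reason`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("prot_acc,pep_seq,pep_score,pep_expect,pep_var_mod_pos",
#'              "P12345,SAPSTR,55,0.001,0.100000.0"), tf)
#' parse_engine_table(tf, "mascot", "case")
#' @export
parse_engine_table <- function(path, engine, sample_label,
                               file_id = basename(path), col_map = NULL) {
  engine <- match.arg(engine, engines)
  sample_label <- match.arg(sample_label, sample_labels)
  if (!file.exists(path)) {
    abort(sprintf("input file does not exist: %s", path))
  }
  reader <- if (engine == "mascot") readr::read_csv else readr::read_tsv
  tab <- tryCatch(
    suppressWarnings(reader(path, show_col_types = FALSE, progress = FALSE)),
    error = function(e) abort(sprintf("unreadable input file %s: %s",
                                      path, conditionMessage(e)))
  )
  if (!is.null(col_map)) {
    for (canonical in names(col_map)) {
      if (col_map[[canonical]] %in% names(tab)) {
        names(tab)[names(tab) == col_map[[canonical]]] <- canonical
      }
    }
  }
  missing <- setdiff(required_cols[[engine]], names(tab))
  if (length(missing) > 0L) {
    abort(sprintf(
      "file %s does not match the %s column layout; missing column(s): %s",
      path, engine, paste(missing, collapse = ", ")
    ))
  }

  get_num <- function(col) {
    if (col %in% names(tab)) suppressWarnings(as.numeric(tab[[col]])) else
      rep(NA_real_, nrow(tab))
  }
  raw <- switch(engine,
    mascot = tibble(
      peptide = as.character(tab$pep_seq),
      acc = as.character(tab$prot_acc),
      mod_str = as.character(tab$pep_var_mod_pos),
      expect = get_num("pep_expect"),
      ion_score = get_num("pep_score"),
      xcorr = NA_real_,
      confidence = NA_real_,
      loc_score = get_num("pep_loc_score"),
      ratio = get_num("pep_ratio")
    ),
    paragon = tibble(
      peptide = as.character(tab$Sequence),
      acc = as.character(tab$Accessions),
      mod_str = as.character(tab$Modifications),
      expect = NA_real_,
      ion_score = NA_real_,
      xcorr = NA_real_,
      confidence = get_num("Conf"),
      loc_score = get_num("LocScore"),
      ratio = get_num("Ratio")
    ),
    sequest_pd = tibble(
      peptide = as.character(tab$Sequence),
      acc = as.character(tab[["Protein Group Accessions"]]),
      mod_str = as.character(tab$Modifications),
      expect = NA_real_,
      ion_score = NA_real_,
      xcorr = get_num("XCorr"),
      confidence = NA_real_,
      loc_score = get_num("LocScore"),
      ratio = get_num("Ratio")
    )
  )

  decode <- switch(engine,
    mascot = parse_mods_mascot,
    paragon = parse_mods_paragon,
    sequest_pd = parse_mods_sequest
  )

  keep <- logical(nrow(raw))
  reasons <- character(nrow(raw))
  mods_list <- vector("list", nrow(raw))
  acc_list <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    pep <- toupper(trimws(raw$peptide[i] %||% ""))
    if (is.na(pep) || !nzchar(pep) || grepl("[^A-Z]", pep)) {
      reasons[i] <- "missing or invalid peptide sequence"
      next
    }
    acc_str <- raw$acc[i]
    if (is.na(acc_str)) acc_str <- ""
    accs <- trimws(strsplit(acc_str, ";", fixed = TRUE)[[1]])
    accs <- accs[!is.na(accs) & nzchar(accs)]
    if (length(accs) == 0L) {
      reasons[i] <- "no protein accession reported"
      next
    }
    mods <- decode(raw$mod_str[i], pep)
    if (is.character(mods)) {
      reasons[i] <- mods
      next
    }
    keep[i] <- TRUE
    raw$peptide[i] <- pep
    mods_list[[i]] <- mods
    acc_list[[i]] <- accs
  }

  hits <- tibble(
    engine = engine,
    sample_label = sample_label,
    file_id = file_id,
    peptide = raw$peptide[keep],
    accessions = acc_list[keep],
    mods = mods_list[keep],
    expect = raw$expect[keep],
    ion_score = raw$ion_score[keep],
    xcorr = raw$xcorr[keep],
    confidence = raw$confidence[keep],
    loc_score = raw$loc_score[keep],
    ratio = raw$ratio[keep]
  )
  attr(hits, "rejects") <- tibble(row = which(!keep),
                                  reason = reasons[!keep])
  hits
}

#' Write hits back out in an engine's canonical dialect
#'
#' The inverse of [parse_engine_table()]; used by the fixture generator and
#' by round-trip tests. All hits must share one engine.
#'
#' @param hits Hit tibble as produced by [parse_engine_table()].
#' @param path Output path.
#' @param engine Engine dialect to write; defaults to the engine of the hits.
#' @return `path`, invisibly.
#' @export
write_engine_table <- function(hits, path, engine = unique(hits$engine)) {
  engine <- match.arg(engine, engines)
  stopifnot(all(hits$engine == engine))
  mod_str <- purrr::map2_chr(hits$mods, hits$peptide, format_mods,
                             engine = engine)
  accs <- purrr::map_chr(hits$accessions, paste, collapse = ";")
  out <- switch(engine,
    mascot = tibble(
      prot_acc = accs, pep_seq = hits$peptide, pep_score = hits$ion_score,
      pep_expect = hits$expect, pep_var_mod_pos = mod_str,
      pep_loc_score = hits$loc_score, pep_ratio = hits$ratio
    ),
    paragon = tibble(
      Accessions = accs, Sequence = hits$peptide, Conf = hits$confidence,
      Modifications = mod_str, LocScore = hits$loc_score, Ratio = hits$ratio
    ),
    sequest_pd = tibble(
      `Protein Group Accessions` = accs, Sequence = hits$peptide,
      Modifications = mod_str, XCorr = hits$xcorr,
      LocScore = hits$loc_score, Ratio = hits$ratio
    )
  )
  if (engine == "mascot") {
    readr::write_csv(out, path, progress = FALSE)
  } else {
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

# ---- filtering -------------------------------------------------------------

#' Apply engine-specific quality-score filters
#'
#' Keeps only hits meeting every configured threshold for their engine:
#' Mascot expect value and (optionally) ion score, Paragon confidence, and a
#' localization score applied to all engines. Hits lacking a score that a set
#' threshold references are rejected row-wise (attribute `"rejects"`) rather
#' than silently dropped. Input order is preserved and the operation is
#' idempotent.
#'
#' @param hits Hit tibble.
#' @param cfg A [filter_config()].
#' @return Filtered hit tibble with attribute `"rejects"` (tibble of `row`
#'   within the input and `reason`).
#' @export
apply_filters <- function(hits, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  n <- nrow(hits)
  keep <- rep(TRUE, n)
  reject <- rep(NA_character_, n)

  need <- function(values, active) active & is.na(values)
  test <- function(values, ok) !is.na(values) & ok

  is_mascot <- hits$engine == "mascot"
  is_paragon <- hits$engine == "paragon"

  if (!is.null(cfg$mascot_expect_max)) {
    miss <- is_mascot & is.na(hits$expect)
    reject[miss & is.na(reject)] <- "mascot expect value absent"
    keep <- keep & !(is_mascot & !miss & hits$expect > cfg$mascot_expect_max)
  }
  if (!is.null(cfg$mascot_ion_score_min)) {
    miss <- is_mascot & is.na(hits$ion_score)
    reject[miss & is.na(reject)] <- "mascot ion score absent"
    keep <- keep &
      !(is_mascot & !miss & hits$ion_score < cfg$mascot_ion_score_min)
  }
  if (!is.null(cfg$paragon_confidence_min)) {
    miss <- is_paragon & is.na(hits$confidence)
    reject[miss & is.na(reject)] <- "paragon confidence absent"
    keep <- keep &
      !(is_paragon & !miss & hits$confidence < cfg$paragon_confidence_min)
  }
  if (!is.null(cfg$localization_score_min)) {
    miss <- is.na(hits$loc_score)
    reject[miss & is.na(reject)] <- "localization score absent"
    keep <- keep & !(!miss & hits$loc_score < cfg$localization_score_min)
  }
  keep <- keep & is.na(reject)

  out <- hits[keep, , drop = FALSE]
  attr(out, "rejects") <- tibble(row = which(!is.na(reject)),
                                 reason = reject[!is.na(reject)])
  out
}

#' Discard hits without a targeted modification
#'
#' Non-phosphorylated and non-acetylated peptides carry no information for a
#' modification-centric comparison and are removed. Modification assignments
#' outside the configured types or target residues are pruned from the
#' retained hits, so downstream event identity is defined over the configured
#' modification universe only.
#'
#' @inheritParams apply_filters
#' @return Subset of `hits`, order preserved, each retaining at least one
#'   targeted modification.
#' @export
discard_unmodified <- function(hits, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  pruned <- purrr::map(hits$mods, function(m) {
    m[m$mod_type %in% cfg$mod_types & m$residue %in% cfg$target_residues, ,
      drop = FALSE]
  })
  keep <- vapply(pruned, nrow, 1L) > 0L
  out <- hits[keep, , drop = FALSE]
  out$mods <- pruned[keep]
  out
}
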