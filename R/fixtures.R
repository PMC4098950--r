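#' Plan a synthetic fixture bundle
#'
#' Describes a synthetic case-control experiment with full ground truth: how
#' many phosphosite events of each uniqueness class to plant, over how many
#' proteins, detected by which engines, with how many peptide-spectrum
#' matches per event. The defaults are the package's reference study
#' conditions — 100 unique-case, 100 unique-control and 300 common events
#' across two search engines — and the seed fixes every random choice, so a
#' plan generates byte-identical bundles on every run.
#'
#' @param n_unique_case,n_unique_control,n_common Events per uniqueness
#'   class.
#' @param n_proteins Number of synthetic proteins the events are spread over.
#' @param protein_length_range Soft length range for assembled proteins;
#'   shorter proteins are padded to the minimum.
#' @param engines Engines simulated, subset of
#'   `c("mascot", "paragon", "sequest_pd")`.
#' @param peptides_per_event_range Range of PSMs realizing one event (common
#'   events always get at least two, one per sample).
#' @param multi_match_fraction Fraction of events whose peptide is planted in
#'   a second protein, exercising the multi-match path.
#' @param acetyl_fraction Fraction of events carrying an acetyl-lysine site
#'   instead of pure phosphorylation.
#' @param quant Logical; generate a pooled quantitative bundle with
#'   per-peptide abundance ratios instead of labeled sample files.
#' @param quant_thresholds The [quant_config()] the ratio distributions are
#'   truncated against: unique-case ratios are drawn strictly above the case
#'   cutoff, unique-control strictly below the control cutoff, common in the
#'   neutral band, so class recovery from ratios is exact by construction.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `"fixture_plan"`.
#' @export
fixture_plan <- function(n_unique_case = 100, n_unique_control = 100,
                         n_common = 300, n_proteins = 80,
                         protein_length_range = c(150, 600),
                         engines = c("mascot", "paragon"),
                         peptides_per_event_range = c(1, 3),
                         multi_match_fraction = 0,
                         acetyl_fraction = 0.05,
                         quant = FALSE,
                         quant_thresholds = quant_config(),
                         seed = 1L) {
  engines <- match.arg(engines, c("mascot", "paragon", "sequest_pd"),
                       several.ok = TRUE)
  stopifnot(
    n_unique_case >= 0, n_unique_control >= 0, n_common >= 0,
    n_unique_case + n_unique_control + n_common > 0,
    n_proteins >= 1, length(protein_length_range) == 2,
    peptides_per_event_range[1] >= 1,
    peptides_per_event_range[2] >= peptides_per_event_range[1],
    multi_match_fraction >= 0, multi_match_fraction <= 1,
    acetyl_fraction >= 0, acetyl_fraction <= 1
  )
  structure(
    list(
      n_unique_case = as.integer(n_unique_case),
      n_unique_control = as.integer(n_unique_control),
      n_common = as.integer(n_common),
      n_proteins = as.integer(n_proteins),
      protein_length_range = as.integer(protein_length_range),
      engines = engines,
      peptides_per_event_range = as.integer(peptides_per_event_range),
      multi_match_fraction = multi_match_fraction,
      acetyl_fraction = acetyl_fraction,
      quant = isTRUE(quant),
      quant_thresholds = quant_thresholds,
      seed = as.integer(seed)
    ),
    class = "fixture_plan"
  )
}

#' @export
print.fixture_plan <- function(x, ...) {
  cat(sprintf(
    "<fixture_plan> %d unique-case / %d unique-control / %d common events over %d proteins; engines: %s; %s mode; seed %d\n",
    x$n_unique_case, x$n_unique_control, x$n_common, x$n_proteins,
    paste(x$engines, collapse = ", "),
    if (x$quant) "quantitative" else "qualitative", x$seed))
  invisible(x)
}

# residue alphabets; ambiguous letters (B, Z, X) are never generated although
# the parsers accept them
aa_no_kr <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N", "P",
              "Q", "S", "T", "V", "W", "Y")
phospho_residues <- c("S", "T", "Y")

random_core <- function(acetyl) {
  len <- sample(9:16, 1)
  chars <- sample(aa_no_kr, len - 1, replace = TRUE)
  chars <- c(chars, sample(c("K", "R"), 1))
  n_sites <- sample(1:2, 1, prob = c(0.75, 0.25))
  pos <- sort(sample(2:(len - 1), n_sites))
  res <- sample(phospho_residues, n_sites, replace = TRUE,
                prob = c(0.8, 0.18, 0.02))
  type <- rep("phospho", n_sites)
  if (acetyl) {
    res[1] <- "K"
    type[1] <- "acetyl"
  }
  chars[pos] <- res
  list(peptide = paste(chars, collapse = ""),
       sites = tibble(pos = pos, residue = res, mod_type = type))
}

random_linker <- function(min_len = 5, max_len = 15) {
  paste(sample(c(aa_no_kr, "K", "R"), sample(min_len:max_len, 1),
               replace = TRUE), collapse = "")
}

draw_ratio <- function(class, qc) {
  switch(class,
    unique_case = runif(1, qc$case_ratio_min * 1.15, qc$case_ratio_min * 3),
    unique_control = runif(1, qc$control_ratio_max * 0.3,
                           qc$control_ratio_max * 0.88),
    common = runif(1, qc$control_ratio_max * 1.08, qc$case_ratio_min * 0.93)
  )
}

build_fixture_once <- function(plan) {
  classes <- rep(c("unique_case", "unique_control", "common"),
                 c(plan$n_unique_case, plan$n_unique_control, plan$n_common))
  n_events <- length(classes)
  accessions <- sprintf("SYNP%04d", seq_len(plan$n_proteins))

  # cores, distinct by construction
  seen <- character()
  cores <- vector("list", n_events)
  for (i in seq_len(n_events)) {
    repeat {
      core <- random_core(acetyl = runif(1) < plan$acetyl_fraction)
      if (!core$peptide %in% seen) break
    }
    seen <- c(seen, core$peptide)
    cores[[i]] <- core
  }
  protein_of <- sample(plan$n_proteins, n_events, replace = TRUE)
  n_multi <- round(plan$multi_match_fraction * n_events)
  multi_events <- if (n_multi > 0) sample(n_events, n_multi) else integer()
  is_multi <- seq_len(n_events) %in% multi_events

  # assemble proteins: padding + (core + linker) per event, in event order
  seqs <- character(plan$n_proteins)
  offsets <- integer(n_events)
  for (p in seq_len(plan$n_proteins)) {
    ev <- which(protein_of == p)
    s <- random_linker(8, 20)
    for (i in ev) {
      offsets[i] <- nchar(s) + 1L
      s <- paste0(s, cores[[i]]$peptide, random_linker())
    }
    seqs[p] <- s
  }
  for (i in multi_events) {
    others <- setdiff(seq_len(plan$n_proteins), protein_of[i])
    p2 <- if (length(others) > 0) sample(others, 1) else protein_of[i]
    seqs[p2] <- paste0(seqs[p2], cores[[i]]$peptide, random_linker())
  }
  short <- nchar(seqs) < plan$protein_length_range[1]
  seqs[short] <- vapply(seqs[short], function(s) {
    paste0(s, paste(sample(c(aa_no_kr, "K", "R"),
                           plan$protein_length_range[1] - nchar(s),
                           replace = TRUE), collapse = ""))
  }, "")

  # every core must occur exactly where planted and nowhere else
  aa_set <- Biostrings::AAStringSet(seqs)
  names(aa_set) <- accessions
  for (i in seq_len(n_events)) {
    m <- Biostrings::vmatchPattern(cores[[i]]$peptide, aa_set)
    total <- sum(lengths(Biostrings::startIndex(m)))
    if (total != 1L + is_multi[i]) return(NULL)
  }

  # realize PSMs
  qc <- plan$quant_thresholds
  p_rng <- plan$peptides_per_event_range
  psms <- vector("list", n_events)
  truth <- vector("list", n_events)
  for (i in seq_len(n_events)) {
    cls <- classes[i]
    acc <- accessions[protein_of[i]]
    prot <- seqs[protein_of[i]]
    core <- cores[[i]]
    off <- offsets[i]
    core_end <- off + nchar(core$peptide) - 1L

    # peptide variants: the core always, optionally one extended form
    variants <- list(c(start = off, end = core_end))
    if (runif(1) < 0.5) {
      ext_l <- sample(0:4, 1)
      ext_r <- sample(0:4, 1)
      st <- max(1L, off - ext_l)
      en <- min(nchar(prot), core_end + ext_r)
      if (st < off || en > core_end) {
        variants <- c(variants, list(c(start = st, end = en)))
      }
    }

    detecting <- plan$engines[runif(length(plan$engines)) < 0.7]
    if (length(detecting) == 0) detecting <- sample(plan$engines, 1)
    m <- sample(p_rng[1]:p_rng[2], 1)
    m <- max(m, length(detecting), if (cls == "common") 2L else 1L)
    psm_engine <- rep(detecting, length.out = m)[sample.int(m)]
    samples <- switch(cls,
      unique_case = rep("case", m),
      unique_control = rep("control", m),
      common = c("case", "control",
                 sample(c("case", "control"), m - 2, replace = TRUE))
    )
    variant_idx <- c(1L, sample(seq_along(variants), m - 1, replace = TRUE))
    rows <- purrr::map(seq_len(m), function(j) {
      v <- variants[[variant_idx[j]]]
      pep <- substr(prot, v[["start"]], v[["end"]])
      eng <- psm_engine[j]
      tibble(
        engine = eng,
        sample_label = if (plan$quant) "case" else samples[j],
        file_id = NA_character_,
        peptide = pep,
        accessions = list(acc),
        mods = list(tibble(pos = core$sites$pos + off - v[["start"]],
                           residue = core$sites$residue,
                           mod_type = core$sites$mod_type)),
        expect = if (eng == "mascot") 10^runif(1, -6, -2.5) else NA_real_,
        ion_score = if (eng == "mascot") runif(1, 35, 90) else NA_real_,
        xcorr = if (eng == "sequest_pd") runif(1, 2, 6) else NA_real_,
        confidence = if (eng == "paragon") runif(1, 99, 100) else NA_real_,
        loc_score = runif(1, 20, 100),
        ratio = if (plan$quant) draw_ratio(cls, qc) else NA_real_
      )
    }) |> bind_rows()
    psms[[i]] <- rows

    abs_sites <- tibble(position = core$sites$pos + off - 1L,
                        residue = core$sites$residue,
                        mod_type = core$sites$mod_type)
    truth[[i]] <- tibble(
      accession = acc,
      site_key = site_key(abs_sites),
      class = cls,
      shared_sequence = core$peptide,
      shared_start = off,
      shared_end = core_end,
      multi_match = is_multi[i],
      n_psms = m,
      sites = list(abs_sites)
    )
  }

  list(
    proteins = tibble(accession = accessions, sequence = seqs,
                      description = sprintf("synthetic protein %d",
                                            seq_len(plan$n_proteins))),
    psms = bind_rows(psms),
    truth = bind_rows(truth)
  )
}

#' Generate a synthetic fixture bundle on disk
#'
#' Writes a complete synthetic experiment — a FASTA proteome, one PSM export
#' per (engine, sample) in that engine's canonical dialect (one pooled export
#' per engine in quantitative mode), a known-site database, a run
#' configuration file, and a ground-truth table listing every planted event's
#' expected class, sites, shared sequence and novelty. Every planted peptide
#' occurs in its assigned protein at the recorded offset and nowhere else
#' (verified during generation), and detection patterns are constructed so
#' each event's class follows from the consensus rule exactly.
#'
#' @param plan A [fixture_plan()].
#' @param dir Output directory (created).
#' @return A list of class `"fixture_bundle"`: `dir`, `plan`, `files` (paths:
#'   `fasta`, `tables` tibble with `path`/`engine`/`sample_label`,
#'   `known_sites`, `ground_truth`, `config`), `truth` (event-level tibble),
#'   and `truth_sites` (site-level tibble with `known` flags).
#' @examples
#' \donttest{
#' bundle <- generate_fixtures(fixture_plan(5, 5, 10, n_proteins = 10,
#'                                          seed = 42), tempfile())
#' bundle$truth
#' }
#' @export
generate_fixtures <- function(plan, dir) {
  stopifnot(inherits(plan, "fixture_plan"))
  max_core <- 16L
  if (plan$protein_length_range[1] < max_core) {
    abort("infeasible plan: peptides would be longer than the shortest protein")
  }
  built <- NULL
  for (attempt in 0:4) {
    set.seed(plan$seed + attempt * 1000003L)
    built <- build_fixture_once(plan)
    if (!is.null(built)) break
  }
  if (is.null(built)) {
    abort("could not realize the fixture plan with unique peptide placements")
  }

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta_path <- file.path(dir, "proteome.fasta")
  write_fasta(built$proteins, fasta_path, dialect = "uniprot")

  # known-site database: each true site known with probability 1/2, plus
  # consistent decoy entries at unobserved positions
  truth_sites <- built$truth |>
    select("accession", "sites") |>
    tidyr::unnest("sites") |>
    distinct(.data$accession, .data$position, .data$residue, .data$mod_type)
  truth_sites$known <- runif(nrow(truth_sites)) < 0.5
  seq_of <- setNames(built$proteins$sequence, built$proteins$accession)
  decoys <- purrr::map(seq_len(max(1L, nrow(truth_sites) %/% 2L)), function(i) {
    acc <- sample(built$proteins$accession, 1)
    pos <- sample(nchar(seq_of[[acc]]), 1)
    res <- substring(seq_of[[acc]], pos, pos)
    if (!res %in% c("S", "T", "Y", "K")) return(NULL)
    tibble(accession = acc, position = pos, residue = res,
           mod_type = if (res == "K") sample(c("phospho", "acetyl"), 1)
                      else "phospho")
  }) |> bind_rows()
  if (nrow(decoys) > 0) {
    decoys <- anti_join(
      decoys, truth_sites,
      by = c("accession", "position", "residue", "mod_type"))
  }
  known <- bind_rows(
    truth_sites[truth_sites$known, c("accession", "position", "residue",
                                     "mod_type")],
    decoys
  ) |> distinct() |> arrange(.data$accession, .data$position)
  known_path <- file.path(dir, "known_sites.tsv")
  readr::write_tsv(known, known_path, col_names = FALSE, progress = FALSE)

  # engine export tables
  psms <- built$psms
  groups <- if (plan$quant) {
    distinct(psms, .data$engine) |> mutate(sample_label = "case")
  } else {
    distinct(psms, .data$engine, .data$sample_label)
  } |> arrange(.data$engine, .data$sample_label)
  tables <- purrr::pmap(groups, function(engine, sample_label) {
    sel <- psms$engine == engine &
      (plan$quant | psms$sample_label == sample_label)
    ext <- if (engine == "mascot") "csv" else "tsv"
    stem <- if (plan$quant) paste0(engine, "_pooled") else
      paste0(engine, "_", sample_label)
    path <- file.path(dir, paste0(stem, ".", ext))
    write_engine_table(psms[sel, , drop = FALSE], path, engine)
    tibble(path = path, engine = engine, sample_label = sample_label)
  }) |> bind_rows()

  truth <- select(built$truth, -"sites") |>
    mutate(event_id = paste(.data$accession, .data$site_key, sep = "|"),
           .before = 1) |>
    arrange(.data$event_id)
  truth_path <- file.path(dir, "ground_truth.tsv")
  readr::write_tsv(truth, truth_path, progress = FALSE)

  config_path <- file.path(dir, "config.yml")
  cfg_lines <- c(
    "fasta: proteome.fasta",
    "known_sites:",
    "  - known_sites.tsv",
    paste0("quant: ", tolower(as.character(plan$quant))),
    "inputs:"
  )
  for (i in seq_len(nrow(tables))) {
    cfg_lines <- c(cfg_lines,
      paste0("  - path: ", basename(tables$path[i])),
      paste0("    engine: ", tables$engine[i]),
      paste0("    sample_label: ", tables$sample_label[i]))
  }
  writeLines(cfg_lines, config_path)

  structure(
    list(
      dir = dir,
      plan = plan,
      files = list(fasta = fasta_path, tables = tables,
                   known_sites = known_path, ground_truth = truth_path,
                   config = config_path),
      truth = built$truth,
      truth_sites = truth_sites
    ),
    class = "fixture_bundle"
  )
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle> %d event(s) in %s\n", nrow(x$truth), x$dir))
  print(x$plan)
  invisible(x)
}
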