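# Shared helpers: a hit constructor mirroring parse_engine_table()'s output
# shape, and one small pre-generated bundle reused across test files.

make_hit <- function(engine = "mascot", sample_label = "case",
                     peptide = "SAPSTR", accessions = "P1",
                     mods = tibble::tibble(pos = 1L, residue = "S",
                                           mod_type = "phospho"),
                     expect = 0.001, ion_score = 50, xcorr = NA_real_,
                     confidence = 99.5, loc_score = 80, ratio = NA_real_,
                     file_id = "f1") {
  tibble::tibble(
    engine = engine, sample_label = sample_label, file_id = file_id,
    peptide = peptide, accessions = list(accessions), mods = list(mods),
    expect = expect, ion_score = ion_score, xcorr = xcorr,
    confidence = confidence, loc_score = loc_score, ratio = ratio
  )
}

# random hit tibble used by round-trip and filtering property tests
random_hits <- function(n, engine = "mascot", seed = 1) {
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      len <- sample(8:14, 1)
      pep <- paste(sample(c("A", "D", "E", "G", "I", "L", "S", "T", "Y", "K",
                            "R", "P", "V"), len, replace = TRUE),
                   collapse = "")
      n_mod <- sample(0:2, 1)
      pos <- if (n_mod > 0) sort(sample(len, n_mod)) else integer()
      res <- if (length(pos)) substring(pep, pos, pos) else character()
      type <- if (length(pos)) {
        ifelse(res == "K", sample(c("acetyl", "phospho"), length(pos), TRUE),
               "phospho")
      } else {
        character()
      }
      make_hit(
        engine = engine,
        sample_label = sample(c("case", "control"), 1),
        peptide = pep,
        accessions = sprintf("P%02d", sample(20, sample(1:2, 1))),
        mods = tibble::tibble(pos = pos, residue = res, mod_type = type),
        expect = if (engine == "mascot") 10^runif(1, -5, -1) else NA_real_,
        ion_score = if (engine == "mascot") runif(1, 10, 90) else NA_real_,
        xcorr = if (engine == "sequest_pd") runif(1, 1, 6) else NA_real_,
        confidence = if (engine == "paragon") runif(1, 90, 100) else NA_real_,
        loc_score = runif(1, 0, 100)
      )
    }) |> dplyr::bind_rows()
  })
}

tiny_plan <- fixture_plan(n_unique_case = 5, n_unique_control = 5,
                          n_common = 10, n_proteins = 10,
                          multi_match_fraction = 0.1, seed = 7)
tiny_bundle <- generate_fixtures(tiny_plan, file.path(tempdir(), "tiny_bundle"))

truth_with_id <- function(bundle) {
  dplyr::mutate(bundle$truth,
                event_id = paste(accession, site_key, sep = "|"))
}

parse_all_bundle <- function(bundle, cfg = filter_config()) {
  hits <- purrr::pmap(bundle$files$tables,
                      function(path, engine, sample_label) {
                        parse_engine_table(path, engine, sample_label)
                      }) |> dplyr::bind_rows()
  discard_unmodified(apply_filters(hits, cfg), cfg)
}

run_bundle <- function(bundle, ...) {
  run_comparison(bundle$files$tables, bundle$files$fasta,
                 bundle$files$known_sites, quiet = TRUE, ...)
}

# unique-protein sets computed directly from a bundle's ground truth
truth_proteins <- function(bundle, class) {
  t <- bundle$truth
  sort(unique(t$accession[t$class == class & !t$multi_match]))
}
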