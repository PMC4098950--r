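test_that("each engine dialect decodes modification strings to residue assignments", {
  mascot <- tempfile(fileext = ".csv")
  writeLines(c(
    "prot_acc,pep_seq,pep_score,pep_expect,pep_var_mod_pos",
    "P12345,SAPSTR,55,0.001,0.100000.0"
  ), mascot)
  h <- parse_engine_table(mascot, "mascot", "case")
  expect_equal(nrow(h), 1L)
  expect_equal(h$peptide, "SAPSTR")
  expect_equal(h$accessions[[1]], "P12345")
  expect_equal(h$expect, 0.001)
  expect_equal(h$mods[[1]],
               tibble::tibble(pos = 1L, residue = "S", mod_type = "phospho"))

  paragon <- tempfile(fileext = ".tsv")
  writeLines(c(
    "Accessions\tSequence\tConf\tModifications",
    "P12345;Q99999\tSAPSTR\t99.4\tPhospho(S)@1; Phospho(T)@5"
  ), paragon)
  h <- parse_engine_table(paragon, "paragon", "control")
  expect_equal(h$accessions[[1]], c("P12345", "Q99999"))
  expect_equal(nrow(h$mods[[1]]), 2L)
  expect_equal(h$mods[[1]]$residue, c("S", "T"))
  expect_equal(h$confidence, 99.4)

  sequest <- tempfile(fileext = ".tsv")
  writeLines(c(
    "Protein Group Accessions\tSequence\tModifications\tXCorr",
    "NP_000001.1\tSAPKTR\tS1(Phospho); K4(Acetyl)\t3.2"
  ), sequest)
  h <- parse_engine_table(sequest, "sequest_pd", "case")
  expect_equal(h$mods[[1]]$mod_type, c("phospho", "acetyl"))
  expect_equal(h$mods[[1]]$pos, c(1L, 4L))
  expect_equal(h$xcorr, 3.2)
})

test_that("unknown column layouts are fatal and name the missing columns", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("sequence,score", "SAPSTR,12"), bad)
  expect_error(parse_engine_table(bad, "mascot", "case"), "pep_seq")
  expect_error(parse_engine_table(tempfile(), "mascot", "case"),
               "does not exist")
})

test_that("undecodable rows become rejects, never silent drops", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "Accessions\tSequence\tConf\tModifications",
    "P1\tSAPSTR\t99\tPhospho(S)@1",
    "P1\tSAPSTR\t99\tPhospho(T)@1",   # residue mismatch at position 1
    "P1\t\t99\tPhospho(S)@1",         # no peptide
    "P1\tSAPSTR\t99\tGarbage",        # bad token
    "\tSAPSTR\t99\t"                  # no accession
  ), f)
  h <- parse_engine_table(f, "paragon", "case")
  rejects <- attr(h, "rejects")
  expect_equal(nrow(h), 1L)
  expect_equal(nrow(rejects), 4L)
  expect_equal(nrow(h) + nrow(rejects), 5L)
  expect_true(any(grepl("mismatch", rejects$reason)))
})

test_that("column mapping hook renames real-world export columns", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("Accession,Peptide,Expect,VarMods",
               "P1,SAPSTR,0.002,0.100000.0"), f)
  h <- parse_engine_table(f, "mascot", "case",
                          col_map = c(prot_acc = "Accession",
                                      pep_seq = "Peptide",
                                      pep_expect = "Expect",
                                      pep_var_mod_pos = "VarMods"))
  expect_equal(h$peptide, "SAPSTR")
  expect_equal(h$expect, 0.002)
})

test_that("write-then-parse round-trips all semantic fields for every engine", {
  for (engine in c("mascot", "paragon", "sequest_pd")) {
    hits <- random_hits(120, engine, seed = match(engine, c(
      "mascot", "paragon", "sequest_pd")))
    path <- tempfile(fileext = if (engine == "mascot") ".csv" else ".tsv")
    write_engine_table(hits, path)
    back <- parse_engine_table(path, engine, "case", file_id = "f1")
    back$sample_label <- hits$sample_label
    expect_equal(nrow(attr(back, "rejects")), 0L)
    expect_equal(back$peptide, hits$peptide)
    expect_equal(back$accessions, hits$accessions)
    expect_equal(purrr::map(back$mods, ~ dplyr::arrange(.x, pos)),
                 purrr::map(hits$mods, ~ dplyr::arrange(.x, pos)))
    for (col in c("expect", "ion_score", "xcorr", "confidence", "loc_score")) {
      expect_equal(back[[col]], hits[[col]], tolerance = 1e-12)
    }
  }
})

test_that("score filters keep passing hits, drop failing ones, preserve order", {
  hits <- dplyr::bind_rows(
    make_hit(expect = 0.001),                       # mascot, under 0.01 cutoff
    make_hit(expect = 0.05),                        # mascot, over cutoff
    make_hit(engine = "paragon", expect = NA, confidence = 95),
    make_hit(engine = "paragon", expect = NA, confidence = 99.5),
    make_hit(engine = "sequest_pd", expect = NA, confidence = NA, xcorr = 3)
  )
  kept <- apply_filters(hits, filter_config())
  expect_equal(kept$expect[kept$engine == "mascot"], 0.001)
  expect_equal(kept$confidence[kept$engine == "paragon"], 99.5)
  expect_equal(nrow(kept), 3L)  # sequest has no engine threshold configured
  expect_equal(kept$engine, c("mascot", "paragon", "sequest_pd"))
})

test_that("a config with no thresholds returns the input unchanged", {
  hits <- random_hits(30, "mascot", seed = 4)
  cfg <- filter_config(mascot_expect_max = NULL, paragon_confidence_min = NULL)
  out <- apply_filters(hits, cfg)
  expect_equal(nrow(out), nrow(hits))
  expect_equal(out$peptide, hits$peptide)
})

test_that("hits missing a referenced score are rejected with a reason", {
  hits <- dplyr::bind_rows(make_hit(expect = NA), make_hit(expect = 0.005))
  out <- apply_filters(hits, filter_config())
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "rejects")$row, 1L)
  expect_match(attr(out, "rejects")$reason, "expect value absent")

  hits <- make_hit(loc_score = NA)
  out <- apply_filters(hits, filter_config(localization_score_min = 50))
  expect_equal(nrow(out), 0L)
  expect_match(attr(out, "rejects")$reason, "localization")
})

test_that("filtering is idempotent and localization cutoff drops low scores", {
  hits <- random_hits(200, "mascot", seed = 5)
  cfg <- filter_config(mascot_ion_score_min = 40,
                       localization_score_min = 30)
  once <- apply_filters(hits, cfg)
  twice <- apply_filters(once, cfg)
  expect_identical(dplyr::as_tibble(once), dplyr::as_tibble(twice))
  expect_true(all(once$ion_score >= 40))
  expect_true(all(once$loc_score >= 30))
})

test_that("unmodified peptides are discarded, modified retained in order", {
  no_mod <- make_hit(mods = tibble::tibble(pos = integer(),
                                           residue = character(),
                                           mod_type = character()))
  one_mod <- make_hit(peptide = "SAPSTR")
  expect_equal(nrow(discard_unmodified(no_mod, filter_config())), 0L)
  expect_equal(nrow(discard_unmodified(one_mod, filter_config())), 1L)

  hits <- random_hits(150, "paragon", seed = 6)
  cfg <- filter_config()
  out <- discard_unmodified(hits, cfg)
  # brute-force keep mask: >= 1 targeted modification
  keep <- vapply(hits$mods, function(m) {
    any(m$mod_type %in% cfg$mod_types & m$residue %in% cfg$target_residues)
  }, TRUE)
  expect_equal(nrow(out), sum(keep))
  # order preserved: output rows are the kept input rows in input order
  expect_equal(out$peptide, hits$peptide[keep])
  expect_equal(out$confidence, hits$confidence[keep])
})

test_that("modification-type settings restrict what counts as modified", {
  both <- make_hit(peptide = "SAPKTR",
                   mods = tibble::tibble(pos = c(1L, 4L),
                                         residue = c("S", "K"),
                                         mod_type = c("phospho", "acetyl")))
  phos_only <- discard_unmodified(both, filter_config(mod_types = "phospho"))
  expect_equal(nrow(phos_only), 1L)
  expect_equal(phos_only$mods[[1]]$mod_type, "phospho")
  acetyl_only <- discard_unmodified(both, filter_config(mod_types = "acetyl"))
  expect_equal(acetyl_only$mods[[1]]$residue, "K")
})
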