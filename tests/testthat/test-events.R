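# builds a minimal mapped-hit row without going through files
mapped_row <- function(accession = "P1", start = 3L, peptide = "SAPSTR",
                       sites = tibble::tibble(position = 3L, residue = "S",
                                              mod_type = "phospho"),
                       engine = "mascot", sample_label = "case",
                       multi_match = FALSE, file_id = "f1",
                       ratio = NA_real_) {
  tibble::tibble(
    engine = engine, sample_label = sample_label, file_id = file_id,
    peptide = peptide, accessions = list(accession),
    mods = list(tibble::tibble(pos = sites$position - start + 1L,
                               residue = sites$residue,
                               mod_type = sites$mod_type)),
    expect = NA_real_, ion_score = NA_real_, xcorr = NA_real_,
    confidence = NA_real_, loc_score = NA_real_, ratio = ratio,
    accession = accession, start = start,
    end = start + nchar(peptide) - 1L, multi_match = multi_match,
    sites = list(sites)
  )
}

test_that("peptides of different lengths with identical sites form one event counted per member", {
  prot <- "MKSAPSTRAAAG"
  site <- tibble::tibble(position = 6L, residue = "S", mod_type = "phospho")
  short <- mapped_row(start = 3L, peptide = substr(prot, 3, 10), sites = site)
  long <- mapped_row(start = 2L, peptide = substr(prot, 2, 12), sites = site,
                     engine = "paragon")
  ev <- build_events(dplyr::bind_rows(short, long))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_members, 2L)
  # shared sequence is the intersection of the two member intervals
  expect_equal(ev$shared_start, 3L)
  expect_equal(ev$shared_end, 10L)
  expect_equal(ev$shared_sequence, substr(prot, 3, 10))
})

test_that("a single peptide yields one event whose shared sequence is itself", {
  ev <- build_events(mapped_row())
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$shared_sequence, "SAPSTR")
  expect_equal(ev$n_members, 1L)
})

test_that("distinct site sets on one protein are distinct events", {
  a <- mapped_row()
  b <- mapped_row(sites = tibble::tibble(position = c(3L, 7L),
                                         residue = c("S", "T"),
                                         mod_type = "phospho"))
  ev <- build_events(dplyr::bind_rows(a, b))
  expect_equal(nrow(ev), 2L)
})

test_that("event grouping equals a brute-force pairwise partition on random peptides", {
  withr::with_seed(31, {
    n <- 200
    rows <- purrr::map(seq_len(n), function(i) {
      acc <- sprintf("P%d", sample(8, 1))
      start <- sample(20, 1)
      len <- sample(6:12, 1)
      pep <- paste(sample(c("A", "S", "T", "G", "L"), len, replace = TRUE),
                   collapse = "")
      k <- sample(1:2, 1)
      pos <- sort(sample(start:(start + len - 1L), k))
      sites <- tibble::tibble(
        position = pos,
        residue = substring(pep, pos - start + 1L, pos - start + 1L),
        mod_type = sample(c("phospho", "acetyl"), k, replace = TRUE)
      )
      mapped_row(accession = acc, start = start, peptide = pep, sites = sites,
                 engine = sample(c("mascot", "paragon"), 1),
                 sample_label = sample(c("case", "control"), 1))
    }) |> dplyr::bind_rows()

    ev <- build_events(rows)
    # brute force: same event iff same accession and identical site sets
    # (site sets pre-sorted once; the partition itself is built pairwise)
    sorted_sites <- purrr::map(rows$sites,
                               ~ dplyr::arrange(.x, position, residue,
                                                mod_type))
    same_event <- function(i, j) {
      rows$accession[i] == rows$accession[j] &&
        identical(sorted_sites[[i]], sorted_sites[[j]])
    }
    group_of <- integer(n)
    next_group <- 0L
    for (i in seq_len(n)) {
      assigned <- FALSE
      for (j in seq_len(i - 1L)) {
        if (same_event(i, j)) {
          group_of[i] <- group_of[j]
          assigned <- TRUE
          break
        }
      }
      if (!assigned) {
        next_group <- next_group + 1L
        group_of[i] <- next_group
      }
    }
    expect_equal(nrow(ev), next_group)
    expect_equal(sum(ev$n_members), n)
    expect_equal(sort(ev$n_members), sort(as.integer(table(group_of))))
  })
})

test_that("the consensus rule matches its examples and totals are partitioned", {
  case_only <- tibble::tibble(engine = "mascot", sample_label = "case", n = 1L)
  expect_equal(classify_uniqueness(case_only), "unique_case")
  both <- tibble::tibble(engine = "mascot",
                         sample_label = c("case", "control"), n = 1L)
  expect_equal(classify_uniqueness(both), "common")
  expect_error(classify_uniqueness(tibble::tibble(
    engine = "mascot", sample_label = "case", n = 0L)), "ill-formed")

  ev <- run_bundle(tiny_bundle)$events
  expect_equal(sum(ev$status == "unique_case") +
                 sum(ev$status == "unique_control") +
                 sum(ev$status == "common"),
               nrow(ev))
})

test_that("consensus labels equal a literal-translation oracle on all 81 presence matrices", {
  # oracle: detected in case by >=1 engine AND in control by no engine, etc.
  oracle <- function(m) {
    detected_case <- any(m[, "case"] >= 1)
    detected_control <- any(m[, "control"] >= 1)
    if (detected_case && !detected_control) return("unique_case")
    if (detected_control && !detected_case) return("unique_control")
    "common"
  }
  grid <- expand.grid(a_case = 0:2, a_control = 0:2,
                      b_case = 0:2, b_control = 0:2)
  grid <- grid[rowSums(grid) > 0, ]
  expect_equal(nrow(grid), 80L)  # the all-zero matrix errors instead
  for (r in seq_len(nrow(grid))) {
    m <- matrix(as.integer(grid[r, ]), nrow = 2, byrow = TRUE,
                dimnames = list(c("engineA", "engineB"),
                                c("case", "control")))
    presence <- tibble::tibble(
      engine = rep(rownames(m), each = 2),
      sample_label = rep(colnames(m), 2),
      n = as.integer(t(m))
    )
    expect_equal(classify_uniqueness(presence), oracle(m))
  }
})

test_that("adding a control detection to a unique-case event makes it common", {
  withr::with_seed(17, {
    for (i in 1:25) {
      n_eng <- sample(1:3, 1)
      engines <- paste0("e", seq_len(n_eng))
      presence <- tidyr::expand_grid(engine = engines,
                                     sample_label = c("case", "control"))
      presence$n <- ifelse(presence$sample_label == "case",
                           sample(0:2, nrow(presence), replace = TRUE), 0L)
      if (sum(presence$n) == 0) presence$n[1] <- 1L
      expect_equal(classify_uniqueness(presence), "unique_case")
      bumped <- presence
      ctrl_slots <- which(bumped$sample_label == "control")
      slot <- ctrl_slots[sample.int(length(ctrl_slots), 1)]
      bumped$n[slot] <- bumped$n[slot] + 1L
      expect_equal(classify_uniqueness(bumped), "common")
    }
  })
})

test_that("swapping case and control labels swaps the unique counts exactly", {
  res <- run_bundle(tiny_bundle)
  swapped_inputs <- tiny_bundle$files$tables
  swapped_inputs$sample_label <- ifelse(swapped_inputs$sample_label == "case",
                                        "control", "case")
  res_swapped <- run_comparison(swapped_inputs, tiny_bundle$files$fasta,
                                tiny_bundle$files$known_sites, quiet = TRUE)
  expect_equal(res_swapped$summary$n_unique_case,
               res$summary$n_unique_control)
  expect_equal(res_swapped$summary$n_unique_control,
               res$summary$n_unique_case)
  expect_equal(res_swapped$summary$n_common, res$summary$n_common)
})

test_that("unique proteins require a unique event with unambiguous members", {
  site <- tibble::tibble(position = 3L, residue = "S", mod_type = "phospho")
  clean <- build_events(mapped_row(accession = "P1", sites = site)) |>
    classify_events()
  prot <- unique_phosphoproteins(clean)
  expect_equal(prot$accession, "P1")
  expect_equal(prot$sample_label, "case")

  ambiguous <- build_events(mapped_row(accession = "P2", sites = site,
                                       multi_match = TRUE)) |>
    classify_events()
  expect_equal(nrow(unique_phosphoproteins(ambiguous)), 0L)

  common_ev <- build_events(dplyr::bind_rows(
    mapped_row(accession = "P3", sites = site),
    mapped_row(accession = "P3", sites = site, sample_label = "control")
  )) |> classify_events()
  expect_equal(nrow(unique_phosphoproteins(common_ev)), 0L)
})

test_that("unique-protein sets equal a brute-force construction on fixture data", {
  res <- run_bundle(tiny_bundle)
  ev <- res$events
  # brute force directly over classified events
  expected_case <- sort(unique(ev$accession[ev$status == "unique_case" &
                                              !ev$any_multi]))
  expected_control <- sort(unique(ev$accession[ev$status == "unique_control" &
                                                 !ev$any_multi]))
  got <- res$proteins
  expect_equal(got$accession[got$sample_label == "case"], expected_case)
  expect_equal(got$accession[got$sample_label == "control"], expected_control)
  # and the fixture ground truth agrees
  expect_equal(expected_case, truth_proteins(tiny_bundle, "unique_case"))
  expect_equal(expected_control,
               truth_proteins(tiny_bundle, "unique_control"))
})

test_that("engine partition matches direct set computation and disjoint exclusives", {
  res <- run_bundle(tiny_bundle)
  part <- engine_partition(res$events)
  for (i in seq_len(nrow(part))) {
    eng <- part$engine[i]
    direct <- res$events$event_id[vapply(res$events$presence, function(p) {
      sum(p$n[p$engine == eng]) > 0
    }, TRUE)]
    expect_setequal(part$detected[[i]], direct)
  }
  excl <- part$exclusive
  if (length(excl) > 1) {
    for (i in seq_along(excl)) {
      for (j in seq_along(excl)) {
        if (i < j) expect_length(intersect(excl[[i]], excl[[j]]), 0L)
      }
    }
  }
  # an event seen by every engine is in all detected sets, no exclusive set
  seen_by_all <- res$events$event_id[vapply(res$events$presence, function(p) {
    length(unique(p$engine[p$n > 0])) == nrow(part)
  }, TRUE)]
  for (id in seen_by_all) {
    expect_true(all(vapply(part$detected, function(d) id %in% d, TRUE)))
    expect_false(any(vapply(part$exclusive, function(d) id %in% d, TRUE)))
  }
})
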