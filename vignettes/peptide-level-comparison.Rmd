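---
title: "Peptide-level comparison of case-control phosphoproteomic search results"
author: "phosphodiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-level comparison of case-control phosphoproteomic search results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphodiff)
```

## The problem

A single LC-MS/MS phosphoproteomics experiment identifies thousands of
phosphopeptides through database search engines such as Mascot, Paragon
(ProteinPilot) or Sequest (Proteome Discoverer). Comparing a stimulated
*case* sample with an unstimulated *control* at the protein level loses the
information that matters most: two samples may share a phosphoprotein while
differing in *which* residues are phosphorylated. Doing the peptide-level
comparison by hand in a spreadsheet is laborious and error-prone, because
the same phosphorylation event is reported as many distinct peptide strings
(missed cleavages, different lengths) and each search engine has its own
export dialect.

phosphodiff automates this comparison. It ingests PSM (peptide-spectrum
match) exports from multiple engines, maps every modified peptide onto
protein coordinates, collapses peptides into *phosphosite equivalence
classes*, classifies each class as unique-to-case, unique-to-control or
common under a multi-engine consensus rule, annotates site novelty against
known-site databases, and emits HTML/TSV reports plus a warning log.

## The model

**Phosphosite equivalence classes (events).** The unit of comparison is not
a peptide string but the pair (protein accession, exact set of modified
sites). Two peptides of different lengths carrying the same phosphosite on
the same protein belong to one event and are counted as two member
detections. The event's representative *shared sequence* is the
intersection of its members' protein intervals, which by construction
always contains every site. Site identity includes the modification type,
so a phosphorylated and an acetylated peptide at the same residue form
distinct events and are reported in separate sections. A peptide carrying
one shared and one extra site has a different site set and therefore forms
its own event — it is classified on the full set, not per site.

**Consensus uniqueness.** With detection counts $n_{e,s}$ for engine $e$
and sample $s$, an event is *unique to the case sample* iff

$$\sum_e n_{e,\mathrm{case}} \ge 1 \quad\text{and}\quad
  \sum_e n_{e,\mathrm{control}} = 0,$$

symmetrically for the control sample, and *common* otherwise. The three
statuses partition the events, so the class counts always sum to the event
total, and relabeling the samples swaps the two unique counts while fixing
the common count.

**Uniquely modified proteins.** A protein is uniquely modified in a sample
iff it owns at least one event with the matching unique status *all of
whose members mapped unambiguously* (no multi-match peptide). Proteins
appearing in both samples' unique sets are the "same protein, different
sites" discoveries that protein-level comparison misses; the report counts
them as the intersection of the two unique-protein sets.

**Quantitative mode.** In iTRAQ/SILAC-style experiments the samples are
pooled before the search and each peptide carries a case/control abundance
ratio instead of a sample label. A ratio strictly above `case_ratio_min` is
treated as a detection in a qualitative case sample, strictly below
`control_ratio_max` as a control detection, and the neutral band (including
exactly 1) as presence in *both* samples, so neutral events classify as
common. The defaults $\sqrt 2 \approx 1.414$ and $1/\sqrt 2 \approx 0.707$
split a two-fold difference symmetrically on the log scale.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `mascot_expect_max` | 0.01 | Mascot expectation-value cutoff (unitless; smaller = better) |
| `mascot_ion_score_min` | off | optional Mascot ion-score floor; applied conjunctively with the expect cutoff when both are set |
| `paragon_confidence_min` | 99 | Paragon peptide confidence floor, percent |
| `localization_score_min` | off | floor for a site-localization score passed through from the exporting software; hits below it (or lacking it) are dropped entirely — phosphodiff does not itself score localization |
| `target_residues` | S, T, Y, K | residues whose modifications are considered |
| `mod_types` | phospho, acetyl | modification universe defining event identity |
| `case_ratio_min` / `control_ratio_max` | 1.414 / 0.707 | quantitative-mode fold-change cutoffs |
| `position_tolerance` | 0 | optional ± residues when matching known-site databases built on other sequence versions |

The engine-score defaults are the thresholds used throughout the package's
worked examples; every value is overridable per run (or with CLI flags).

## Design choices where the design was open

* **Mascot thresholds are conjunctive.** When both an expect cutoff and an
  ion-score floor are configured, a hit must satisfy both. Applying only
  one would silently weaken whichever filter the user thought was active.
* **Localization cutoff drops, never demotes.** A hit below the
  localization floor is removed rather than kept with a caveat; dropping is
  the conservative reading and keeps event identity crisp.
* **Primary accession.** Engines report an ordered accession list; the
  first accession present in the FASTA that contains the peptide is
  primary. If none resolves, a whole-database scan rescues the hit with an
  `ACCESSION_MISMATCH` warning — a flagged rescue beats silent loss. All
  resolvable proteins still count toward the multi-match flag.
* **Multi-position peptides.** A peptide occurring at several positions
  (or in several proteins) maps to the lowest position of its primary
  protein — a deterministic tie-break — and is flagged `multi_match`, which
  excludes it from unique-protein attribution but not from event
  classification.
* **Sequences are uppercased before comparison; I and L stay distinct.**
  Conflating isoleucine and leucine would merge sites on genuinely
  different inferred sequences.
* **Known-site matching is exact and residue-checked** (a serine entry
  never validates an observed threonine at the same coordinate), guarding
  against coordinate drift between FASTA versions; a positional tolerance
  exists as an explicit opt-in, default off. Databases are unioned with
  per-site provenance, so load order can never change an annotation.
* **Replicates pool.** Files sharing a sample label are processed as one
  batch; per-file provenance survives into the report rows.

## Numerical and degenerate-input conventions

Coordinates are 1-based inclusive throughout ("Ser-3" style). Fold-change
comparisons are strict inequalities, so a ratio exactly on a cutoff falls
in the neutral band. Residue percentages are computed exactly and rounded
to one decimal for display; the rounded values sum to 100 within ±0.2. An
event whose member intervals somehow failed to overlap would fall back to
the minimal site-covering interval with a warning (this cannot arise for
members that each cover their own sites, but the guard keeps the invariant
explicit). Empty inputs degrade gracefully: an empty known-site database
marks every site novel, zero events yield zero percentages without
division errors, and a clean run still writes an (empty) log file so
"no warnings" is distinguishable from "no logging".

## The synthetic data generator

Real search-engine exports cannot be redistributed, so the package
generates its own experiments with complete ground truth
([`fixture_plan()`] / [`generate_fixtures()`]). The generator:

* assembles proteins from planted core peptides (9–16 residues,
  tryptic-like: ending in K/R, no internal K/R except acetyl-lysine sites)
  joined by random linkers, then *verifies* that every core occurs exactly
  once in the proteome (twice for planted multi-match events), so mapping
  ground truth is exact by construction;
* realizes each event as 1–3 PSMs, optionally including a longer variant
  peptide with the identical site set, so the shared-sequence logic is
  exercised;
* constructs detection patterns that realize the planned class under the
  consensus rule (common events always get at least one PSM per sample);
* in quantitative mode draws ratios from truncated bands — strictly above
  the case cutoff for unique-case events, strictly below the control
  cutoff for unique-control, inside the neutral band for common — so class
  recovery from ratios alone is exact;
* plants half of the true sites in the known-site database (plus
  sequence-consistent decoy entries), fixing novelty ground truth;
* writes everything in the same dialects the parsers read, plus a run
  `config.yml`, under a single seed that makes bundles byte-identical
  across runs.

The reference plan — the package's default study conditions — is 100
unique-case, 100 unique-control and 300 common events over 80 proteins
with two engines (Mascot and Paragon), a scale at which the whole pipeline
runs in seconds. Unit tests use a smaller 5/5/10 bundle; the acceptance
script runs the full reference plan qualitatively and quantitatively.

**What the generator does not emulate.** Scores are sampled only to
exercise filters, not from realistic score distributions; there are no
decoy identifications, no missed-cleavage ladders beyond the planned
variants, no ambiguous site localization, no isoforms or sequence
variants, and no retention-time or spectral information. Passing tests
therefore demonstrate the bookkeeping — parsing, mapping, grouping,
consensus classification, novelty annotation, reporting — not the
correctness of upstream identifications, which phosphodiff consumes as
given.

## A small worked example

```{r example, eval = FALSE}
bundle <- generate_fixtures(
  fixture_plan(n_unique_case = 5, n_unique_control = 5, n_common = 10,
               n_proteins = 10, seed = 7),
  tempdir())
res <- run_comparison(bundle$files$tables, bundle$files$fasta,
                      bundle$files$known_sites, quiet = TRUE)
res
glance(res)
autoplot(res)
```

## Known limitations

* Exact substring mapping only: no isoform-aware, gapped or semi-tryptic
  mapping, and no handling of amino-acid substitutions between the search
  database and the supplied FASTA.
* The engine dialects are frozen canonical layouts; real-world exports
  with different column names need the `col_map` hook.
* No statistical testing of abundance differences, no FDR estimation, and
  no site-localization scoring — thresholds are pass-through filters on
  scores computed upstream.
* Novelty annotation is flat-file only; no live database queries.
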