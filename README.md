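# phosphodiff

Peptide-level case–control comparison of phosphoproteomic (and acetylomic)
database-search results.

## The problem

Mass-spectrometry phosphoproteomics identifies thousands of phosphopeptides
per experiment, but comparing a stimulated **case** sample against a
**control** at the protein level hides the interesting biology: two samples
often share a phosphoprotein while differing in *which residues* are
phosphorylated. Doing the peptide-level comparison by hand is slow and
error-prone — the same phosphorylation event appears as many different
peptide strings, and every search engine (Mascot, Paragon/ProteinPilot,
Sequest/Proteome Discoverer) exports its own table dialect.

phosphodiff is for proteomics researchers who have PSM exports from one or
more search engines and want an automated, reproducible answer to: *which
modification events are unique to the case sample, which to the control,
and which are common — and which of those sites are novel?*

## The method

- **Phosphosite equivalence classes.** Peptides are mapped onto protein
  coordinates from a FASTA proteome and grouped by (accession, exact set of
  modified sites). Peptides of different lengths with identical sites are
  one *event*; the event's reported sequence is the intersection of its
  members' intervals (the shared sequence).
- **Multi-engine consensus.** With detection counts `n[engine, sample]`, an
  event is unique to the case sample iff it was detected in the case by at
  least one engine and in the control by **no** engine (symmetrically for
  control); anything else is common. The three classes partition the
  events.
- **Uniquely modified proteins.** A protein is uniquely modified in a
  sample iff it owns a unique event whose members all mapped unambiguously.
  Proteins present in both samples' unique sets are the "same protein,
  different sites" cases.
- **Quantitative mode.** For pooled iTRAQ/SILAC-style data, per-peptide
  case/control ratios are thresholded (defaults `> 1.414` case-enriched,
  `< 0.707` control-enriched, neutral band → present in both samples) and
  the qualitative machinery applies unchanged.
- **Novelty annotation.** Sites are compared exactly — accession, position,
  residue and modification type — against unioned flat-file known-site
  databases; unmatched sites are flagged novel.

Outputs: a self-contained HTML report (unique-case rows red, unique-control
blue, common black; modified residues underlined; novel sites bold; all
information duplicated in machine-readable `data-*` attributes), a TSV of
the same rows, per-engine statistics files, a summary table and a tagged
warning log.

## Worked example

Every run needs labeled PSM exports and a FASTA; the package can generate a
fully synthetic experiment with known ground truth:

```r
library(phosphodiff)

bundle <- generate_fixtures(
  fixture_plan(n_unique_case = 5, n_unique_control = 5, n_common = 10,
               n_proteins = 10, seed = 7),
  tempdir())

res <- run_comparison(bundle$files$tables, bundle$files$fasta,
                      bundle$files$known_sites, quiet = TRUE)
res
#> <phospho_comparison>
#>   mode:     qualitative
#>   inputs:   46 PSM(s) parsed, 46 passed filters, 46 modified, 46 mapped
#>   events:   20 (5 unique-case, 5 unique-control, 10 common)
#>   proteins: 3 unique in case, 4 in control, 1 in both sets
#>   warnings: 0
```

The 46 PSMs collapse into 20 events; the planted 5/5/10 class design is
recovered exactly. The `1 in both sets` protein is one identified in both
samples but with different phosphorylation sites. `tidy()` returns the
report rows:

```r
dplyr::select(head(tidy(res), 4), accession, status, marked_sequence,
              sites, novelty, n_S, n_T)
#> # A tibble: 4 × 7
#>   accession status         marked_sequence   sites   novelty       n_S   n_T
#>   <chr>     <chr>          <chr>             <chr>   <chr>       <int> <int>
#> 1 SYNP0001  unique_control NINQPCAQEMS*PQK   S30     known           1     0
#> 2 SYNP0001  unique_control TFYCANHCAGSS*TTCK S53     novel           1     0
#> 3 SYNP0002  common         DK*CEITYISCR      K17     novel           0     0
#> 4 SYNP0003  common         SK*FGSS*MMMAK     K28;S32 novel;known     1     0
```

`*` marks a modified residue in the shared sequence; `sites` gives absolute
protein coordinates (e.g. `S30` = phosphoserine at residue 30); `novelty`
says whether each site is in the loaded known-site databases. `glance(res)`
gives the one-row totals, `autoplot(res)` the class-count figure, and
`write_outputs(res, dir)` the HTML/TSV/log files.

There is also a shell interface:

```sh
exec/phosphodiff fixtures --out demo --seed 7
exec/phosphodiff run --config demo/config.yml --out demo/output
```

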