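Package: phosphodiff
Title: Peptide-Level Case-Control Comparison of Phosphoproteomic Search Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of peptide-spectrum-match exports from multiple
    database search engines (Mascot, Paragon/ProteinPilot, Sequest/Proteome
    Discoverer) for phosphoproteomic and acetylomic case-control studies.
    Modified peptides are filtered by engine-specific quality scores, mapped
    onto protein coordinates from a FASTA proteome, collapsed into phosphosite
    equivalence classes, and classified as unique to the case sample, unique
    to the control sample, or common under a multi-engine consensus rule.
    Supports a quantitative mode in which fold-change ratios are thresholded
    to assign enriched peptides to a sample, novelty annotation against known
    modification-site databases, HTML and TSV comparison reports, and a
    synthetic fixture generator with full ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
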