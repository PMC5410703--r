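Package: gbmtools
Title: Gene-Body Methylation Analysis of Whole-Genome Bisulfite Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing per-cytosine bisulfite-sequencing call
    tables: weighted DNA-methylation levels by sequence context (CG, CHG,
    CHH) at genome, gene and window resolution; 20-window gene-body
    metaplots with upstream/downstream flanks; classification of
    mCG-enriched (gene-body methylated, gbM) genes by an exact binomial
    enrichment test against a coding-sequence background with
    Benjamini-Hochberg false-discovery-rate control; binomial read thinning
    to emulate shallow (~1x) coverage and a deep-vs-1x linear calibration
    with inverse-prediction 95% confidence intervals; and a six-frame
    longest-ORF transcript filter. Includes a ground-truthed synthetic
    methylome generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
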