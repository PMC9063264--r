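Package: xdeconv
Title: Expression-Based Species Deconvolution for Mixed Human-Mouse Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing barnyard (mixed human and mouse) droplet
    single-cell RNA-seq libraries aligned to a combined two-species
    reference. Quantifies cross-species read misalignment and exonic
    multi-mapping by comparing combined-reference and species-matching
    count matrices; classifies droplets as human cells, mouse cells or
    cross-species doublets from reference-atlas expression correlations
    with read-majority tie breaking and optional copy-number support for
    aneuploid tumour cells; applies per-sample quality control and
    artificial-doublet intrasample doublet detection; estimates and
    subtracts per-cell ambient RNA contamination; and scores batch
    integration with kNN-based acceptance (kBET-style) and inverse
    Simpson (LISI-style) metrics. Includes a generative barnyard
    simulator that emits combined and species-matching views of the same
    droplets together with an exact per-read fate ledger, so every stage
    of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    data.table,
    igraph,
    irlba,
    RANN,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
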