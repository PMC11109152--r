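Package: chromclone
Title: Clone-Resolved Chromatin Accessibility Analytics for Paired Single-Cell Multiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics for studying how clone-of-origin epigenetic states shape the
    response to a genetic perturbation in paired single-cell ATAC + RNA (multiome)
    data. Implements background-matched motif deviation Z-scores, permutation-tested
    peak-gene cis-regulatory links and domains of regulatory chromatin (DORCs),
    co-accessible peak modules from TF high/low fold-change profiles, pseudobulk
    negative-binomial Wald differential accessibility, kNN neighborhood localization,
    a clone Functional Perturbation Score, and a lineage-barcode clonal abundance
    pipeline with error-correction clustering. Ships a synthetic paired-multiome
    generator with planted ground truth (bifurcating myeloid trajectory, TF programs,
    cis-linked genes, knockout effects, heritable clone offsets, barcoded reads) so
    every stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    IRanges,
    Biostrings,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
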