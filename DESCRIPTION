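Package: phosphoprimer
Title: Differential Phosphoproteomics and Priming-Site Analysis for Gsk-3
    Kinase Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to identify candidate substrates of Gsk-3 family kinases
    from quantitative site-level phosphoproteomics. Implements moderated
    differential testing with empirical-Bayes variance shrinkage and
    permutation-based false discovery rate control, median normalization and
    left-censored normal imputation, phospho-occupancy normalization to the
    proteome, scanning of the (S/T)XXX(S/T) kinase consensus with
    priming-site classification and phosphopeptide multiplicity statistics,
    transcript-protein integration (correlation, quadrant classes, gene-set
    overlap tests), and a synthetic multi-omics data generator with planted
    kinase-substrate and regulon structure for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    limma,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
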