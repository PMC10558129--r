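Package: stemchrom
Title: Promoter Architecture and Chromatin Analysis of Stem-Cell,
    Tissue-Specific, and Constitutive Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for distinguishing stem-cell, tissue-specific, and
    constitutive gene regulation from replicated expression data and
    chromatin profiling. Implements TPM-based expression-rule gene
    classification with a pluggable differential-expression engine,
    TSS-centered ATAC/H3K4me3 metaprofiles and a fragment-midpoint
    nucleosome-occupancy proxy, replicate-consensus peak filtering and
    genomic feature assignment, promoter sequence statistics (positional
    base composition, poly(dT) tract detection, k-mer enrichment, tandem
    repeat scanning, and PWM motif scanning), Hi-C A/B compartment calling
    with white-strip correction and KR balancing, and automated detection
    and distance-based colony clustering of labeled cells in calibrated
    image stacks. A synthetic-data generator plants known promoter
    architectures, expression classes, compartment structure, and cell
    colonies so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    DESeq2,
    dplyr,
    generics,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
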