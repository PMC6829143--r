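Package: cnvforest
Title: Supervised Detection of Copy-Number Variants from Read-Depth Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects tandem duplications and deletions in short-read
    sequencing data by classifying genomic sub-windows with a random-forest
    classifier trained on simulated copy-number variants. Computes six
    standardized coverage and breakpoint-read statistics per sub-window,
    assembles focal-plus-flanking feature vectors, simulates pooled
    training data with planted duplications and deletions, combines
    replicate classifiers into bootstrap-consensus calls to suppress false
    positives, and estimates per-window copy number against
    coverage-rounding and smoothed-regression baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    matrixStats,
    stats,
    utils,
    withr,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    GenomicAlignments
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
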