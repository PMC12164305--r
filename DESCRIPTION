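Package: fstscan
Title: Selection-Signature Scanning and Population Structure for Multi-Breed SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for post-variant-calling population
    genetics on multi-breed SNP panels: staged genotype quality control with an
    auditable removal ledger, identity-by-state distances with neighbor-joining
    trees and classical MDS, pairwise weighted Weir-Cockerham FST, and a
    differential-selection-region scan that combines per-SNP FST under the
    Nicholson drift model, allelic Fisher's exact tests with Bonferroni
    correction, two-tier quantile thresholds, and a seed-and-extend region
    detector, followed by gene annotation of detected regions against a GFF3
    file. A Balding-Nichols simulator generates multi-population genotype
    panels with planted selected regions so the whole pipeline can be
    exercised and benchmarked without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    ape,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
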