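Package: mtdrift
Title: Mitochondrial Genome Deletion Dynamics and Adaptation Phenotyping in
    Experimentally Evolving Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how clonal yeast populations adapt to
    mitochondrial superoxide stress through regulated segmental deletion of
    their mitochondrial genome. Provides an individual-based simulator of
    serial-bottleneck experimental evolution with diminishing-returns
    epistasis (the null model of nuclear-mutation-driven adaptation),
    doubling-time extraction from colony growth curves with spatial control
    normalization, read-depth copy-number and aneuploidy calling with mtDNA
    segmentation and petite (rho) classification, delta-delta-Ct relative
    copy number from qPCR tables, a permutation enrichment test for
    top-ranked strain sets, and synthetic-data generators with known ground
    truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    readr,
    rlang,
    minpack.lm,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
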