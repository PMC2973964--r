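Package: rvCollapse
Title: Rare-Variant Collapsing Association Tests for Case-Control and
    Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Region-based collapsing (burden) association analysis of low
    frequency and rare variants. Markers below a minor-allele-frequency
    cutoff are pooled within genes (with optional flanks) or sliding
    windows into a single "super-locus", and each individual is classified
    as carrier or non-carrier of at least one rare minor allele. Carrier
    status is tested against a binary trait with Pearson's chi-squared
    test, Fisher's exact test under a minimum-cell rule, and permutation
    empirical p-values, or against a quantitative trait with linear
    regression on carrier status and a two-sample t-test. Includes readers
    and writers for linkage-format MAP/PED and gene-coordinate files, a
    Hardy-Weinberg fixture simulator with planted effects, Manhattan and
    trait-distribution plots, and end-to-end per-chromosome drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
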