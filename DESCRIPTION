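Package: efburden
Title: Etiological-Fraction Burden Testing, Variant Clustering and
    EF-Calibrated ACMG/AMP Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative variant interpretation for Mendelian disease
    from case-control cohort counts. Computes odds ratios and etiological
    fractions (with confidence intervals and Fisher exact tests) for rare
    variant classes, detects sub-genic protein regions enriched for case
    variants with an unsupervised sliding-window binomial scan (automatic
    window-size selection, multiple-testing correction, merging and
    boundary trimming), derives disease-specific allele-frequency rarity
    filters (maximum credible allele frequency, filtering allele
    frequency), and applies a semi-quantitative, EF-calibrated tiered
    ACMG/AMP rule engine to classify variants. Includes seeded
    synthetic-cohort generators for benchmarking every component against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
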