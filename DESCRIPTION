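Package: mrscreen
Title: Two-Sample Mendelian Randomisation Screening of Summary-Level GWAS Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation screens over panels of
    summary-level GWAS outcomes, built around a small genetic instrument such as the
    SERPINA6/A1 cortisol instrument used to screen 42 circulating cytokines.
    Provides summary-statistic reading and effect-allele harmonisation, instrument
    construction and strength diagnostics (genome-wide significance selection, greedy
    LD pruning, per-variant F-statistics and variance explained), Wald-ratio and
    multiplicative random-effects inverse-variance weighted estimation, simple and
    weighted median and MR-Egger sensitivity estimators, an MR-PRESSO global,
    outlier and distortion test, Cochran's Q heterogeneity diagnostics,
    Bonferroni-classified multi-outcome reporting with forest-plot export, and a
    synthetic two-sample summary-statistics generator with known causal effect and
    pleiotropy structure so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
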