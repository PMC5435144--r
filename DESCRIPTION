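Package: screenval
Title: Validation Analysis for Dichotomous Screening Scales
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end validation pipeline for dichotomous screening
    instruments scored against a gold-standard criterion. Implements
    internal consistency (KR-20), test-retest reliability (intraclass
    correlation with its ANOVA F statistic), convergent validity
    (Spearman rank correlation), Fisher-z sample-size calculation,
    factorability diagnostics for binary items (phi and tetrachoric
    correlation matrices, Kaiser-Meyer-Olkin measure, Bartlett's test of
    sphericity, iterated principal-axis one-factor loadings), ROC
    analysis with Hanley-McNeil standard errors, prevalence-adjusted
    predictive values, and decision-theoretic cost-minimizing cut-off
    selection. A seeded two-parameter logistic item-response simulator
    generates synthetic cohorts with a correlated criterion count so the
    whole pipeline is testable without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
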