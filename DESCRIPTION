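Package: dlrplan
Title: Diagnostic Likelihood Ratios for Outcome Validation Summaries and
    Database Study Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantitative bias analysis when planning a
    comparative cohort database study whose outcome is identified by an
    imperfect phenotype algorithm. Summarizes outcome validation studies
    (sensitivity, specificity, prevalence, predictive values, and the
    positive and negative diagnostic likelihood ratios, with exact
    Clopper-Pearson and Katz log-scale confidence intervals), projects the
    expected positive predictive value and the expected risk-ratio bias of
    a planned study from the positive diagnostic likelihood ratio,
    back-solves the likelihood ratio from PPV-only validation reports,
    derives plausible likelihood-ratio spans from collections of
    algorithms, and checks the closed forms by Monte-Carlo simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
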