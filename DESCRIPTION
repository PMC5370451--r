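Package: ntriss
Title: Trauma Survival Probability with TRISS-Variant Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trauma survival-probability modelling with three
    TRISS-variant equations (NTRISS-like, TRISS SpO2, NTRISS-like SpO2):
    anatomical (ISS, NISS) and physiological (RTS-style coded) injury
    scoring, scoring of registry records with published two-center
    coefficient sets, re-derivation of coefficients on new cohorts via
    weighted logistic regression, validation through ROC/AUC with DeLong
    variance and paired model comparison, severity-stratified evaluation,
    two-center cohort comparison statistics, and a synthetic trauma-registry
    generator with a known logistic survival truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
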