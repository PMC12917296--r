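Package: rxtraject
Title: Adherence and Drug-Utilisation Pattern Analysis for Pharmacy Dispensing Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs treatment trajectories of new users of
    anti-hyperlipidemic monotherapy (statins and fibrates) from longitudinal
    pharmacy dispensing records. Implements new-user cohort construction with
    lookback and exclusion windows, supply-based coverage reconstruction with a
    capped stockpile carryover, proportion-of-days-covered adherence metrics
    (yearly, binary at 0.8, prevalence by year, 3-year window), classification
    of drug-utilisation patterns (continuation, discontinuation, switch,
    add-on), equivalent-dose tiering of statin regimens, and a statistical
    layer: multivariable and Lasso logistic risk-prediction models with
    AUC/sensitivity/specificity and Hosmer-Lemeshow calibration, Kaplan-Meier
    curves of adherence transition, and inverse-probability-weighted Cox
    regression with optional time-dependent effects. Ships a synthetic
    dispensing-record generator with planted covariate effects and trajectory
    archetypes so every stage can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    survival,
    glmnet,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
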