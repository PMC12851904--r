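Package: quasivax
Title: Quasi-Experimental Analysis of Date-of-Birth Threshold Vaccination Rollouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing vaccination programmes rolled out with strict
    date-of-birth eligibility thresholds, as natural experiments for downstream
    health outcomes. Implements a local-polynomial regression-discontinuity
    engine (sharp intent-to-treat and fuzzy complier-average effects via
    two-stage least squares) with triangular kernel weights, plug-in
    MSE-optimal bandwidth selection and robust bias-corrected inference; a
    birth-season difference-in-differences estimator with its parallel-trends
    pretest; gender-interaction instrumental-variable models, comorbidity-based
    severity scores with median-split subgroups, and delta-method relative
    effects; a falsification suite (placebo thresholds, pre-period outcomes,
    baseline balance, negative controls, robustness grids); and a synthetic
    linked electronic-health-record cohort generator with potential-outcome
    bookkeeping so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    sandwich,
    lmtest,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
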