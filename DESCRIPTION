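Package: lifemsm
Title: Time-Inhomogeneous Multistate Modelling of Lifetime Coronary
    Artery Disease Risk
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates age-specific one-year transition probabilities
    among cardiometabolic health states (health, hypertension,
    hyperlipidemia, diabetes and their combinations, coronary artery
    disease, death) from long-format longitudinal health records using
    per-age logistic regressions, smooths the age-varying coefficients
    with tricube distance and inverse-variance weighted local polynomial
    regression, and composes the smoothed annual probabilities into
    10-year, 30-year and remaining-lifetime absolute risks of coronary
    artery disease with and without an imputed statin treatment effect.
    Includes a synthetic longitudinal cohort simulator with known
    ground-truth transition models, bootstrap uncertainty for
    projections, and an evaluation battery (stratified calibration RMSE,
    net reclassification, threshold-age analysis, time-dependent
    concordance, cumulative AUC and precision-recall).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
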