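Package: pvpassport
Title: Plasma-Volume-Aware Interpretation of Athlete Biological Passport
    Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for incorporating plasma-volume (PV) information into the
    hematological module of the Athlete Biological Passport (ABP). Estimates
    plasma volume at every visit from a routine complete blood count plus
    anthropometrics with a retrainable regression model, computes per-visit
    adaptive individual reference limits for hemoglobin concentration and
    the OFF-score with an empirical-Bayes surrogate of the ABP Bayesian
    model, corrects the hemoglobin limits for fluid shifts through a
    sex-weighted relative plasma-volume change while preserving the original
    interval width, overlays plasma-volume z-scores on longitudinal
    profiles, reclassifies atypical passport findings explained by plasma
    volume, and quantifies per-marker leverage of the estimator with a
    perturbation sensitivity analysis. A physiologically coupled synthetic
    cohort generator with ground-truth plasma volume, confounder events and
    doping scenarios makes every stage testable without access to athlete
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    glmnet,
    jsonlite,
    mgcv,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
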