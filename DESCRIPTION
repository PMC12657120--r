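Package: hladose
Title: Rejection-Risk Modelling for HLA Match and Immunosuppressant Dose
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing kidney-transplant rejection risk as a joint
    function of low-resolution HLA match fraction and daily tacrolimus dose.
    Provides cohort CSV input/output with completeness checking, a seeded
    synthetic-cohort generator, the dose-uniformity validation stage
    (Shapiro-Wilk, Levene, one-way ANOVA), per-stratum constrained
    ridge-penalized logistic dose-response fitting with cross-validated
    penalty selection, and derived risk metrics (absolute, relative and
    expected rejection-risk reduction) with bootstrap confidence intervals
    and ROC/AUC discrimination diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    car
Config/testthat/edition: 3
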