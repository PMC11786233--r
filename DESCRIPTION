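Package: uticausal
Title: Comparative Effectiveness of Antibiotics for Uncomplicated UTI from
    OMOP-Shaped Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating the average treatment effect of
    first-line versus alternative antibiotics for uncomplicated urinary tract
    infection from insurance-claims tables shaped like the OMOP common data
    model. Builds episode cohorts with a configurable inclusion/exclusion
    cascade, constructs expert and automatically time-windowed confounder
    sets, labels fixed-window binary endpoints with right-censoring
    indicators, fits treatment-propensity and observation-probability models
    by cross-validated model selection, and estimates inverse-probability
    weighted (IPW x IPCW) risk differences with symmetric propensity trimming,
    person-clustered bootstrap confidence intervals, and negative-control
    outcome diagnostics. Ships a synthetic-claims simulator with a known
    treatment effect, confounding by indication, and covariate-dependent
    censoring so every stage is testable without access to private data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    ranger,
    xgboost,
    yaml,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    arrow,
    ggplot2,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
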