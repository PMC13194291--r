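Package: tcsurv
Title: Training-Set Conditionally Valid Lower Prediction Bounds for
    Right-Censored Survival Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs covariate-dependent lower prediction bounds (LPBs)
    for right-censored time-to-event outcomes with asymptotic training-set
    conditional (PAC-style) validity, without requiring censoring times to
    be observed.  Coverage of a candidate bound is estimated with a
    semiparametric one-step estimator built on the efficient influence
    function of the coverage functional, combining a conditional survival
    model for the event time and one for the censoring time; the estimator
    is doubly robust and supports Wald confidence lower bounds on coverage.
    A data-driven rule selects the quantile-level tuning parameter from a
    grid so that the selected bound retains the target coverage with the
    requested confidence.  Includes conditional survival and censoring
    model fitting (product-limit, Weibull and log-normal accelerated
    failure time, Cox proportional hazards, random survival forest, and
    cross-validated selection among these), a synthetic data generator
    with oracle access to the truth for six benchmark settings, and
    evaluation utilities (empirical coverage, average LPB, PAC proportion
    with Wilson intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    ranger,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
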