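Package: mrtengage
Title: Micro-Randomized Trial Analysis of Notification Effects on App Engagement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing micro-randomized
    trials (MRTs) of push notifications in behaviour change apps. Provides a
    synthetic three-arm trial generator with daily 8 PM randomization and an
    absorbing disengagement process; sessionization of raw screen-view logs
    (30-minute inactivity rule) and derivation of binary proximal engagement
    outcomes and time-varying covariates; the estimator for the marginal
    excursion effect (EMEE) of a time-varying binary treatment on a binary
    proximal outcome on the relative-risk scale, with weighted-centered
    estimating equations, damped Newton-Raphson solving and small-sample
    corrected sandwich variance; Kaplan-Meier and log-rank comparison of time
    to disengagement across notification policies; and analytic two-proportion
    sample-size and simulation-based power calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    tibble,
    readr,
    survival,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
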