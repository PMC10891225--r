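Package: tvtpanel
Title: Time-Varying Treatment Weighting and Staggered Difference-in-Differences Estimation for Panel Data
Version: 0.1.0
Authors@R:
    person("tvtpanel", "developers", email = "tvtpanel@example.org", role = c("aut", "cre"))
Description: Tools for estimating causal effects of staggered, absorbing
    (once-on, stays-on) treatments in long-format panel data. Implements
    stabilized inverse-probability-of-treatment weights for average treatment
    effect (ATE) estimands and odds-type weights for group-time average
    treatment effects on the treated (ATT), marginal structural models fit by
    weighted least squares, change-score ("hybrid") weighted estimators, and
    group-time difference-in-differences estimators with never-treated or
    not-yet-treated control groups. Includes a structural-equation simulator
    with four canonical confounding setups (time-invariant or time-varying
    confounders, measured or unmeasured, with treatment-confounder feedback),
    a counterfactual truth oracle based on intervention simulation with common
    exogenous draws, and a Monte Carlo study harness that summarizes bias and
    standard error of every estimator across simulation replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
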