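Package: dynlandmark
Title: Dynamic Landmarking Diagnostics for Propensity-Score-Matched
    Survival Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-hoc diagnostics for hazard ratios estimated from
    propensity-score-matched time-to-event data. Dynamic Landmarking
    sorts a matched cohort by follow-up time, repeatedly deletes the
    earliest observations, refits a treatment-only Cox model, and tracks
    the balance of omitted covariates through the sum of squared
    z-differences (SSQ). The joint behaviour of the treatment-effect and
    SSQ trajectories distinguishes built-in selection bias (omitted
    prognostic factors, a consequence of the non-collapsibility of the
    hazard ratio) from confounding bias (covariates omitted from the
    propensity-score model). Includes maximum-likelihood propensity-score
    estimation, greedy 1:1 nearest-neighbour caliper matching on the
    logit scale, pair-stratified Cox fitting, a rule-based bias
    classifier, and a Weibull proportional-hazards simulation engine for
    validating the diagnostics under known data-generating processes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
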