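# Shared Monte-Carlo runs for the acceptance checks, computed once per test
# session and cached (several criteria interrogate the same scenarios).

mc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = mc_cache)) assign(key, force(expr), envir = mc_cache)
  get(key, envir = mc_cache)
}

# Censoring rate calibrated to ~10% under a given scenario's event model.
rate10_for <- function(config, key) {
  cached(paste0("rate10_", key),
         as.numeric(calibrate_censor_rate(config, target = 0.10)))
}

# The four canonical strong-effect scenarios (role of U), 10% censoring,
# n = 5000, rho = 0, betaZ = log 3, 100 replicates each. Seeds fixed per
# scenario.
canonical_config <- function(role, reps = 100) {
  pars <- switch(role,
    independent = list(alphaU = 0, betaU = 0, seed = 104L),
    prognostic  = list(alphaU = 0, betaU = log(3), seed = 101L),
    instrument  = list(alphaU = log(3), betaU = 0, seed = 103L),
    confounder  = list(alphaU = log(3), betaU = log(3), seed = 102L)
  )
  cfg <- scenario_config(n = 5000, reps = reps, seed = pars$seed,
                         alphaU = pars$alphaU, betaU = pars$betaU,
                         betaZ = log(3))
  cfg$censor_rate <- rate10_for(cfg, role)
  cfg
}

canonical_run <- function(role, reps = 100) {
  cached(paste0("run_", role), run_scenario(canonical_config(role, reps)))
}

expected_label <- c(
  independent = "no_bias_indicated",
  prognostic = "builtin_selection_suspected",
  instrument = "instrument_omitted",
  confounder = "confounding_suspected"
)

# Step-0-only Monte Carlo: simulate, match, pair-stratified fit, balance of U.
mc_step0 <- function(config) {
  seeds <- child_seeds(config$seed, config$reps)
  purrr::map_dfr(seq_len(config$reps), function(r) {
    set.seed(seeds[r])
    cohort <- simulate_cohort(config, seed = NA)
    matched <- match_cohort(cohort, "X")
    fit <- fit_cox_pair_stratified(matched)
    bal <- balance_report(matched, "U")
    tibble::tibble(rep = r, matched_n = nrow(matched),
                   log_hr = fit$log_hr, se = fit$se,
                   ssq = attr(bal, "ssq"))
  })
}
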