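#' Simulation scenario configuration
#'
#' Parameters of the non-randomized-cohort data-generating process used
#' throughout the package: a measured confounder X and an omitted covariate U
#' are correlated standard normals, treatment is assigned by the logistic model
#' `logit(p) = alpha0 + alphaX * X + alphaU * U`, latent event times follow a
#' Weibull proportional-hazards model with hazard
#' `h(t | Z, X, U) = gamma * lambda * t^(gamma - 1) * exp(betaZ*Z + betaX*X + betaU*U)`,
#' and censoring times (if any) are exponential with rate `censor_rate`.
#'
#' Defaults are the strong-confounding reference scenario: n = 5000,
#' `alpha0 = -1.21`, `alphaX = log 3`, `betaX = log 3`, `betaZ = log 3`,
#' Weibull `lambda = 0.01`, `gamma = 1.5`, no censoring. The zero patterns of
#' `alphaU`/`betaU` determine the causal role of U, exposed by
#' [covariate_role()]: independent (both 0), prognostic factor (`alphaU = 0`,
#' `betaU != 0`), instrumental variable (`alphaU != 0`, `betaU = 0`),
#' confounder (both nonzero).
#'
#' @param n cohort size (>= 10).
#' @param reps number of replicate datasets.
#' @param seed master integer seed; replicate r uses a child seed derived
#'   deterministically from `(seed, r)` (see [child_seeds()]).
#' @param alpha0,alphaX,alphaU treatment-model intercept and log-odds effects.
#' @param betaZ,betaX,betaU log-hazard effects of treatment, X, and U.
#' @param rhoXU correlation of X and U, in \[-1, 1\].
#' @param weibull_lambda,weibull_gamma Weibull scale and shape, both > 0.
#' @param censor_rate exponential censoring rate, >= 0 (0 = no censoring).
#' @return A named list of class `scenario_config`.
#' @export
scenario_config <- function(n = 5000, reps = 1, seed = 1L,
                            alpha0 = -1.21, alphaX = log(3), alphaU = 0,
                            betaZ = log(3), betaX = log(3), betaU = 0,
                            rhoXU = 0,
                            weibull_lambda = 0.01, weibull_gamma = 1.5,
                            censor_rate = 0) {
  if (n < 10) abort("n must be >= 10")
  if (reps < 1) abort("reps must be >= 1")
  if (abs(rhoXU) > 1) abort("|rhoXU| must be <= 1")
  if (weibull_lambda <= 0 || weibull_gamma <= 0) {
    abort("weibull_lambda and weibull_gamma must be > 0")
  }
  if (censor_rate < 0) abort("censor_rate must be >= 0")
  structure(
    list(n = as.integer(n), reps = as.integer(reps), seed = as.integer(seed),
         alpha0 = alpha0, alphaX = alphaX, alphaU = alphaU,
         betaZ = betaZ, betaX = betaX, betaU = betaU, rhoXU = rhoXU,
         weibull_lambda = weibull_lambda, weibull_gamma = weibull_gamma,
         censor_rate = censor_rate),
    class = "scenario_config"
  )
}

#' Causal role of the omitted covariate U in a scenario
#'
#' @param config a [scenario_config()].
#' @return One of `"independent"`, `"prognostic"`, `"instrument"`,
#'   `"confounder"`, from the zero pattern of `alphaU` and `betaU`.
#' @export
covariate_role <- function(config) {
  a <- config$alphaU != 0
  b <- config$betaU != 0
  if (!a && !b) "independent"
  else if (!a && b) "prognostic"
  else if (a && !b) "instrument"
  else "confounder"
}

#' Deterministic child seeds for replicate datasets
#'
#' @param seed master integer seed.
#' @param reps number of replicates.
#' @return Integer vector of `reps` seeds, each below 2^31.
#' @export
child_seeds <- function(seed, reps) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, reps)
}

#' Draw correlated standard-normal covariates X and U
#'
#' Generated through the Cholesky factor of the 2x2 correlation matrix, so each
#' is marginally standard normal and `cor(X, U)` converges to `rho`.
#'
#' @param n number of subjects.
#' @param rho target correlation, |rho| <= 1.
#' @return A tibble with columns `X`, `U`. Uses the current RNG stream.
#' @export
sample_covariates <- function(n, rho = 0) {
  if (abs(rho) > 1) abort("|rho| must be <= 1")
  X <- rnorm(n)
  U <- rho * X + sqrt(1 - rho^2) * rnorm(n)
  tibble::tibble(X = X, U = U)
}

#' Assign treatment from the logistic allocation model
#'
#' `Z_i ~ Bernoulli(plogis(alpha0 + alphaX * X_i + alphaU * U_i))`.
#'
#' @param X,U covariate vectors of equal length.
#' @param alpha0,alphaX,alphaU logistic model coefficients.
#' @return Integer 0/1 vector.
#' @export
sample_treatment <- function(X, U, alpha0, alphaX = 0, alphaU = 0) {
  if (length(X) != length(U)) abort("X and U must have the same length")
  p <- plogis(alpha0 + alphaX * X + alphaU * U)
  rbinom(length(X), 1L, p)
}

#' Draw latent Weibull proportional-hazards event times
#'
#' Inverse-transform sampling: `T = (-log(V) / (lambda * exp(lp)))^(1/gamma)`
#' with `V ~ Uniform(0,1)` and linear predictor
#' `lp = betaZ*Z + betaX*X + betaU*U`, which realises the hazard
#' `gamma * lambda * t^(gamma-1) * exp(lp)`.
#'
#' @param Z,X,U treatment and covariate vectors.
#' @param betaZ,betaX,betaU log-hazard coefficients.
#' @param lambda,gamma Weibull scale and shape, both > 0.
#' @return Positive numeric vector of latent event times.
#' @export
sample_event_times <- function(Z, X, U, betaZ = 0, betaX = 0, betaU = 0,
                               lambda = 0.01, gamma = 1.5) {
  if (lambda <= 0 || gamma <= 0) abort("lambda and gamma must be > 0")
  lp <- betaZ * Z + betaX * X + betaU * U
  (-log(runif(length(Z))) / (lambda * exp(lp)))^(1 / gamma)
}

#' Apply independent exponential censoring
#'
#' @param latent_times positive latent event times.
#' @param censor_rate exponential rate (mean censoring time `1/rate`); 0 means
#'   no censoring.
#' @return A tibble with `time` (observed follow-up) and `event`
#'   (1 = event, 0 = censored).
#' @export
apply_censoring <- function(latent_times, censor_rate = 0) {
  if (censor_rate < 0) abort("censor_rate must be >= 0")
  if (censor_rate == 0) {
    return(tibble::tibble(time = latent_times,
                          event = rep(1L, length(latent_times))))
  }
  C <- rexp(length(latent_times), censor_rate)
  tibble::tibble(time = pmin(latent_times, C),
                 event = as.integer(latent_times <= C))
}

#' Simulate one replicate cohort from a scenario
#'
#' Composes [sample_covariates()], [sample_treatment()],
#' [sample_event_times()] and [apply_censoring()] under the scenario's
#' parameters. The returned cohort carries a [covariate_spec()] declaring X and
#' U continuous, so it drops straight into [balance_report()] and
#' [dynamic_landmark()].
#'
#' @param config a [scenario_config()].
#' @param replicate which replicate to generate (1-based); its seed is
#'   `child_seeds(config$seed, replicate)[replicate]`.
#' @param seed overrides the derived seed; `NA` leaves the RNG stream untouched
#'   (for callers that manage seeding themselves).
#' @return A validated cohort tibble (`id`, `treatment`, `time`, `event`,
#'   `X`, `U`).
#' @export
simulate_cohort <- function(config = scenario_config(), replicate = 1L,
                            seed = NULL) {
  if (is.null(seed)) seed <- child_seeds(config$seed, replicate)[replicate]
  if (!is.na(seed)) set.seed(seed)
  n <- config$n
  xu <- sample_covariates(n, config$rhoXU)
  Z <- sample_treatment(xu$X, xu$U, config$alpha0, config$alphaX, config$alphaU)
  T_lat <- sample_event_times(Z, xu$X, xu$U, config$betaZ, config$betaX,
                              config$betaU, config$weibull_lambda,
                              config$weibull_gamma)
  obs <- apply_censoring(T_lat, config$censor_rate)
  cohort <- tibble::tibble(
    id = seq_len(n), treatment = as.integer(Z),
    time = obs$time, event = obs$event, X = xu$X, U = xu$U
  )
  validate_cohort(cohort, spec = covariate_spec(c("X", "U"), "continuous"))
  attr(cohort, "covariate_spec") <- covariate_spec(c("X", "U"), "continuous")
  attr(cohort, "scenario_config") <- config
  cohort
}

#' Calibrate the exponential censoring rate to a target proportion
#'
#' The printed pairing of censoring parameters to censoring proportions is not
#' reproducible from the stated event-time model alone, so target proportions
#' are achieved by monotone bisection: the censored fraction of a large probe
#' cohort (fixed probe seed, default n = 1e5) is driven to within `tol` of
#' `target`.
#'
#' @param config a [scenario_config()]; all parameters except `censor_rate` are
#'   taken from it.
#' @param target desired censored fraction, in (0, 1).
#' @param probe_n probe cohort size.
#' @param probe_seed fixed seed for the probe draws.
#' @param tol convergence tolerance on the achieved fraction.
#' @return The calibrated rate, with the achieved censored fraction attached as
#'   attribute `"achieved"`.
#' @export
calibrate_censor_rate <- function(config = scenario_config(), target,
                                  probe_n = 1e5, probe_seed = 20240101L,
                                  tol = 0.01) {
  if (!(target > 0 && target < 1)) abort("target must lie in (0, 1)")
  probe_cfg <- config
  probe_cfg$n <- as.integer(probe_n)
  probe_cfg$censor_rate <- 0
  probe <- simulate_cohort(probe_cfg, seed = probe_seed)
  latent <- probe$time
  set.seed(probe_seed + 1L)
  Cq <- runif(probe_n)  # shared uniforms: censored fraction is monotone in rate
  frac_at <- function(rate) mean(-log(Cq) / rate < latent)
  lo <- 1e-8; hi <- 1
  while (frac_at(hi) < target) hi <- hi * 10
  for (i in 1:60) {
    mid <- sqrt(lo * hi)
    f <- frac_at(mid)
    if (abs(f - target) < tol / 2) break
    if (f < target) lo <- mid else hi <- mid
  }
  rate <- mid
  structure(rate, achieved = frac_at(rate))
}
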