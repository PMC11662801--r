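test_that("covariate sampler delivers standard-normal margins and the target correlation", {
  set.seed(11)
  xu <- sample_covariates(1e5, rho = 0.6)
  expect_gt(stats::ks.test(xu$X, "pnorm")$p.value, 0.001)
  expect_gt(stats::ks.test(xu$U, "pnorm")$p.value, 0.001)
  expect_lt(abs(cor(xu$X, xu$U) - 0.6), 0.02)

  set.seed(12)
  xu0 <- sample_covariates(1e5, rho = 0)
  expect_lt(abs(cor(xu0$X, xu0$U)), 0.02)

  set.seed(13)
  xu1 <- sample_covariates(100, rho = 1)
  expect_equal(xu1$X, xu1$U, tolerance = 1e-12)
  expect_error(sample_covariates(10, rho = 1.2), "rho")
})

test_that("treatment allocation follows the logistic model", {
  set.seed(21)
  xu <- sample_covariates(2e5, 0)
  z0 <- sample_treatment(xu$X, xu$U, alpha0 = 0)
  expect_lt(abs(mean(z0) - 0.5), 0.01)
  z_lo <- sample_treatment(xu$X, xu$U, alpha0 = -20)
  expect_lt(mean(z_lo), 1e-3)

  # independent oracle: E[expit(-1.21 + log(3) Z)] for Z ~ N(0,1) by quadrature
  target <- stats::integrate(function(z) plogis(-1.21 + log(3) * z) * dnorm(z),
                             -Inf, Inf)$value
  set.seed(22)
  xu <- sample_covariates(1e6, 0)
  z <- sample_treatment(xu$X, xu$U, alpha0 = -1.21, alphaX = log(3))
  expect_lt(abs(mean(z) - target), 0.002)
  expect_error(sample_treatment(1:3, 1:2, 0), "length")
})

test_that("treated prevalence is monotone in the intercept", {
  set.seed(23)
  xu <- sample_covariates(5e4, 0)
  fracs <- vapply(c(-2, -1, 0, 1), function(a0) {
    set.seed(99)
    mean(sample_treatment(xu$X, xu$U, a0, log(3), 0))
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("event times realise the Weibull proportional-hazards model", {
  set.seed(31)
  n <- 1e5
  z <- numeric(n)
  T1 <- sample_event_times(z, z, z, lambda = 0.01, gamma = 1.5)
  expect_true(all(T1 > 0))
  # closed-form Weibull median (ln 2 / lambda)^(1/gamma)
  expect_lt(abs(median(T1) - (log(2) / 0.01)^(1 / 1.5)), 0.3)

  # hazard doubling: S2(t) = S1(t)^2 on a time grid
  set.seed(32)
  T2 <- sample_event_times(rep(1, n), z, z, betaZ = log(2),
                           lambda = 0.01, gamma = 1.5)
  grid <- quantile(T1, c(0.2, 0.4, 0.6, 0.8))
  S1 <- vapply(grid, function(t) mean(T1 > t), numeric(1))
  S2 <- vapply(grid, function(t) mean(T2 > t), numeric(1))
  expect_equal(S2, S1^2, tolerance = 0.02)

  # gamma = 1 reduces to the exponential distribution
  set.seed(33)
  T3 <- sample_event_times(z, z, z, lambda = 0.25, gamma = 1)
  ks <- suppressWarnings(stats::ks.test(T3, "pexp", 0.25))
  expect_lt(unname(ks$statistic), 0.01)
  expect_error(sample_event_times(z, z, z, lambda = -1), "lambda")
})

test_that("exponential censoring behaves at the boundaries and in between", {
  tt <- c(1, 2, 3)
  out <- apply_censoring(tt, 0)
  expect_equal(out$event, c(1L, 1L, 1L))
  expect_equal(out$time, tt)

  set.seed(41)
  heavy <- apply_censoring(rep(10, 1e4), 1e4)
  expect_gt(mean(1 - heavy$event), 0.999)

  # symmetric competing exponentials: half the subjects censored
  set.seed(42)
  T <- rexp(1e5, 1)
  out <- apply_censoring(T, 1)
  expect_lt(abs(mean(1 - out$event) - 0.5), 0.01)
  expect_error(apply_censoring(tt, -1), "censor_rate")
})

test_that("simulate_cohort is deterministic in the seed and shaped correctly", {
  cfg <- scenario_config(n = 5000, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 5000)
  expect_named(a, c("id", "treatment", "time", "event", "X", "U"))
  expect_equal(cohort_covariate_spec(a)$name, c("X", "U"))

  c2 <- simulate_cohort(cfg, replicate = 2)
  expect_false(identical(c2$time, a$time))
  expect_true(all(child_seeds(7, 100) < 2^31))
})

test_that("covariate roles derive from the alphaU/betaU zero pattern", {
  expect_equal(covariate_role(scenario_config(alphaU = 0, betaU = 0)), "independent")
  expect_equal(covariate_role(scenario_config(alphaU = 0, betaU = log(3))), "prognostic")
  expect_equal(covariate_role(scenario_config(alphaU = log(2), betaU = 0)), "instrument")
  expect_equal(covariate_role(scenario_config(alphaU = log(2), betaU = log(2))), "confounder")
})

test_that("adjusted Cox fit recovers the simulated conditional effect", {
  # with no omitted structure, a Cox model on treatment and X is consistent
  cfg <- scenario_config(n = 2000, alphaU = 0, betaU = 0, betaZ = log(2),
                         seed = 51, reps = 60)
  ests <- vapply(seq_len(cfg$reps), function(r) {
    co <- simulate_cohort(cfg, replicate = r)
    unname(coef(survival::coxph(survival::Surv(time, event) ~ treatment + X,
                                data = co, ties = "breslow"))[1])
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - log(2)), 3 * mc_se)
})

test_that("proportional hazards hold by construction", {
  co <- simulate_cohort(scenario_config(n = 2e4, betaU = log(3),
                                        alphaU = log(2), seed = 61))
  fit <- survival::coxph(survival::Surv(time, event) ~ treatment + X + U,
                         data = co, ties = "breslow")
  zph <- survival::cox.zph(fit)
  expect_gt(zph$table["GLOBAL", "p"], 0.001)
})

test_that("censoring-rate calibration hits its target and is monotone", {
  toy <- scenario_config(n = 100, alpha0 = 0, alphaX = 0, betaZ = 0,
                         betaX = 0, betaU = 0, weibull_lambda = 1,
                         weibull_gamma = 1)
  r50 <- calibrate_censor_rate(toy, 0.5, probe_n = 2e5)
  expect_lt(abs(as.numeric(r50) - 1), 0.05)  # symmetric Exp/Exp closed form

  cfg <- scenario_config(betaU = log(3))
  r10 <- calibrate_censor_rate(cfg, 0.10)
  expect_true(attr(r10, "achieved") > 0.09 && attr(r10, "achieved") < 0.11)
  r80 <- calibrate_censor_rate(cfg, 0.80)
  expect_gt(as.numeric(r80), as.numeric(r10))
  expect_error(calibrate_censor_rate(cfg, 1.2), "target")
})
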