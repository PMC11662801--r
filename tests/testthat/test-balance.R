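test_that("continuous z-difference matches closed forms and printed summaries", {
  # means differing by 1 with unit variances, n = 100 per arm: 1/sqrt(0.02)
  expect_equal(z_continuous(1, 1, 100, 0, 1, 100), sqrt(50), tolerance = 1e-12)
  expect_equal(z_continuous(5, 2, 50, 5, 3, 60), 0)

  for (fx in surgical_summaries) {
    z <- z_continuous(fx$a[1], fx$a[2]^2, fx$a[3], fx$b[1], fx$b[2]^2, fx$b[3])
    expect_lt(abs(z - fx$z), 0.02)
  }
  expect_error(z_continuous(1, 0, 10, 2, 0, 10), "zero denominator")
  expect_error(z_continuous(1, 1, 1, 2, 1, 10), "n >= 2")

  # aggregate: the SSQ implied by four printed unmatched rows matches the
  # sum of squares of the printed z-differences
  unmatched <- surgical_summaries[c("weight", "euroscore2", "age_unmatched")]
  ssq_ours <- sum(vapply(unmatched, function(fx) {
    z_continuous(fx$a[1], fx$a[2]^2, fx$a[3], fx$b[1], fx$b[2]^2, fx$b[3])^2
  }, numeric(1)))
  ssq_printed <- sum(vapply(unmatched, function(fx) fx$z^2, numeric(1)))
  expect_lt(abs(ssq_ours - ssq_printed) / ssq_printed, 0.01)
})

test_that("binary z-difference matches closed form and the printed sex row", {
  expect_equal(z_binary(0.6, 100, 0.5, 100), 0.1 / 0.07, tolerance = 1e-4)
  expect_equal(z_binary(0.3, 40, 0.3, 50), 0)
  # published female proportions: magnitude 4.62, orientation treated - control
  z <- z_binary(328 / 607, 607, 836 / 1929, 1929)
  expect_lt(abs(abs(z) - 4.62), 0.02)
  expect_error(z_binary(1, 10, 0, 10), "degenerate")
  expect_error(z_binary(1.2, 10, 0.5, 10), "proportions")
})

test_that("ordinal z is a standardized rank statistic with the right direction", {
  expect_equal(z_ordinal(c(10, 20, 30), c(10, 20, 30)), 0, tolerance = 1e-12)
  # group a entirely above group b
  expect_gt(z_ordinal(c(0, 0, 50), c(50, 0, 0)), 5)
  # two-level ordinal agrees with the binary z within 2%
  zb <- z_binary(0.6, 100, 0.5, 100)
  zo <- z_ordinal(c(40, 60), c(50, 50))
  expect_lt(abs(zo - zb) / abs(zb), 0.02)
  expect_error(z_ordinal(c(10, 0), c(5, 0)), "one level")
  expect_error(z_ordinal(c(10), c(5)), "levels")
})

test_that("nominal z returns per-level indicator statistics", {
  expect_equal(z_nominal(c(10, 10, 10), c(10, 10, 10)), c(0, 0))
  # 2-level nominal reduces to the binary z of level 2
  expect_equal(z_nominal(c(40, 60), c(50, 50)), z_binary(0.6, 100, 0.5, 100))
  # 3-level toy against element-wise indicator arithmetic
  a <- c(10, 10, 10); b <- c(20, 5, 5)
  oracle <- vapply(2:3, function(l) {
    p_a <- a[l] / sum(a); p_b <- b[l] / sum(b)
    (p_a - p_b) / sqrt(p_a * (1 - p_a) / sum(a) + p_b * (1 - p_b) / sum(b))
  }, numeric(1))
  expect_equal(z_nominal(a, b), oracle, tolerance = 1e-12)
})

test_that("balance_report aggregates z^2 into SSQ with correct df bookkeeping", {
  set.seed(71)
  n <- 200
  co <- tibble::tibble(
    id = 1:(2 * n), treatment = rep(c(1L, 0L), each = n),
    time = rexp(2 * n) + 0.01, event = 1L,
    x1 = rnorm(2 * n), flag = rbinom(2 * n, 1, 0.4),
    nyha = sample(c("I", "II", "III"), 2 * n, TRUE),
    site = sample(c("a", "b", "c", "d"), 2 * n, TRUE)
  )
  spec <- covariate_spec(
    c("x1", "flag", "nyha", "site"),
    c("continuous", "binary", "ordinal", "nominal"),
    list(NULL, NULL, c("I", "II", "III"), c("a", "b", "c", "d"))
  )
  rep <- balance_report(co, spec$name, spec = spec)
  expect_equal(attr(rep, "k"), 1 + 1 + 1 + 3)
  expect_equal(attr(rep, "ssq"), sum(rep$z^2), tolerance = 1e-12)
  expect_equal(nrow(rep), 6)
  expect_equal(glance(rep)$k, 6)

  # identical arms: a covariate constant everywhere is flagged NA, df counted
  co2 <- dplyr::mutate(co, const = 1)
  spec2 <- covariate_spec(c("x1", "const"), "continuous")
  rep2 <- balance_report(co2, c("x1", "const"), spec = spec2)
  expect_true(is.na(rep2$z[rep2$name == "const"]))
  expect_equal(attr(rep2, "k"), 2)
})

test_that("SSQ is invariant to affine rescaling and antisymmetric in arm labels", {
  set.seed(72)
  co <- simulate_cohort(scenario_config(n = 600, alphaU = log(2), seed = 72))
  r1 <- balance_report(co, c("X", "U"))
  co2 <- dplyr::mutate(co, X = 3.7 * X - 12)
  attr(co2, "covariate_spec") <- cohort_covariate_spec(co)
  r2 <- balance_report(co2, c("X", "U"))
  expect_equal(attr(r1, "ssq"), attr(r2, "ssq"), tolerance = 1e-12)

  swapped <- dplyr::mutate(co, treatment = 1L - treatment)
  attr(swapped, "covariate_spec") <- cohort_covariate_spec(co)
  r3 <- balance_report(swapped, c("X", "U"))
  expect_equal(r3$z, -r1$z, tolerance = 1e-12)
  expect_equal(attr(r3, "ssq"), attr(r1, "ssq"), tolerance = 1e-12)
})

test_that("SSQ is chi-square calibrated under exchangeable arms", {
  set.seed(73)
  k <- 5; reps <- 300; n <- 150
  ssqs <- vapply(seq_len(reps), function(r) {
    co <- tibble::as_tibble(c(
      list(id = 1:(2 * n), treatment = rep(c(1L, 0L), each = n),
           time = rep(1, 2 * n), event = rep(1L, 2 * n)),
      setNames(replicate(k, rnorm(2 * n), simplify = FALSE), paste0("v", 1:k))
    ))
    spec <- covariate_spec(paste0("v", 1:k), "continuous")
    attr(balance_report(co, spec$name, spec = spec), "ssq")
  }, numeric(1))
  expect_lt(abs(mean(ssqs) / k - 1), 0.1)
})
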