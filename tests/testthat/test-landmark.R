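test_that("follow-up sort is ascending with events before censored at ties", {
  co <- tibble::tibble(
    id = 1:4, treatment = c(1L, 0L, 1L, 0L),
    time = c(3, 1, 2, 2), event = c(1L, 1L, 0L, 1L), x = rnorm(4)
  )
  s <- sort_by_followup(co)
  expect_equal(s$time, c(1, 2, 2, 3))
  expect_equal(s$id[2:3], c(4L, 3L))  # event first at the tie
  expect_identical(sort_by_followup(s)$id, s$id)  # idempotent
})

test_that("delete_earliest removes by follow-up order regardless of status", {
  co <- tibble::tibble(id = 1:4, treatment = c(1L, 0L, 1L, 0L),
                       time = c(1, 2, 3, 4), event = c(0L, 1L, 0L, 1L))
  del <- delete_earliest(co, 2)
  expect_equal(del$landmark_time, 2)
  expect_equal(del$cohort$time, c(3, 4))
  expect_error(delete_earliest(co, 4), "smaller")
  one <- delete_earliest(co, 3)
  expect_equal(nrow(one$cohort), 1)
})

test_that("trajectory has the expected step arithmetic and termination", {
  co <- pair_cohort(a = 30, b = 20)
  co$U <- rnorm(100)
  attr(co, "covariate_spec") <- covariate_spec("U", "continuous")
  traj <- dynamic_landmark(co, omitted = "U", step = 10,
                           stop_min_n = 40, stop_min_events = 1,
                           stop_min_informative = 1)
  # 1 + floor((n0 - n_min)/M) steps: 100 -> 90 -> ... -> 40
  expect_equal(nrow(traj), 1 + floor((100 - 40) / 10))
  expect_true(all(diff(traj$n_remaining) < 0))
  expect_true(all(diff(traj$landmark_time) >= 0))
  expect_equal(attr(traj, "termination_reason"), "min_size_reached")

  # deleting everything in one step leaves only the initial step
  traj1 <- dynamic_landmark(co, omitted = "U", step = 100)
  expect_equal(nrow(traj1), 1)
  expect_equal(attr(traj1, "termination_reason"), "exhausted")

  expect_error(dynamic_landmark(co, omitted = character(0)), "omitted")
})

test_that("each step equals a de novo fit and balance on the remaining subjects", {
  set.seed(101)
  matched <- match_cohort(
    simulate_cohort(scenario_config(n = 800, betaU = log(2), seed = 101)), "X")
  traj <- dynamic_landmark(matched, omitted = "U", step = 60,
                           stop_min_n = 200)
  s <- sort_by_followup(matched)
  for (j in c(2, 4)) {
    remaining <- s[-seq_len((j - 1) * 60), ]
    attr(remaining, "covariate_spec") <- cohort_covariate_spec(matched)
    ref_fit <- fit_cox_pair_stratified(remaining)
    ref_bal <- balance_report(remaining, "U")
    expect_equal(traj$log_hr[j], ref_fit$log_hr, tolerance = 1e-12)
    expect_equal(traj$ssq_omitted[j], attr(ref_bal, "ssq"), tolerance = 1e-12)
    expect_equal(traj$n_remaining[j], nrow(remaining))
  }
})

test_that("trajectories are bit-identical under identical inputs and seeds", {
  cfg <- scenario_config(n = 600, betaU = log(2), seed = 102)
  run <- function() {
    set.seed(5)
    matched <- match_cohort(simulate_cohort(cfg), "X")
    dynamic_landmark(matched, omitted = "U", step = 0.05)
  }
  t1 <- run(); t2 <- run()
  expect_identical(tidy(t1), tidy(t2))
})

test_that("orphaned partners stay for balance but not for the stratified likelihood", {
  co <- pair_cohort(a = 8, b = 6)
  co$U <- rnorm(nrow(co))
  attr(co, "covariate_spec") <- covariate_spec("U", "continuous")
  s <- sort_by_followup(co)
  del <- delete_earliest(s, 1)  # removes one pair member, partner orphaned
  orphan_strata <- names(which(table(del$cohort$stratum) == 1))
  expect_length(orphan_strata, 1)
  with_orphan <- fit_cox_pair_stratified(del$cohort)
  no_orphan <- fit_cox_pair_stratified(
    del$cohort[!del$cohort$stratum %in% orphan_strata, ])
  expect_equal(with_orphan$log_hr, no_orphan$log_hr, tolerance = 1e-12)
  # balance still counts the orphan
  bal <- balance_report(del$cohort, "U")
  expect_equal(attr(bal, "n_treated") + attr(bal, "n_control"),
               nrow(del$cohort))

  # drop_orphans removes the partner as well
  traj <- dynamic_landmark(co, omitted = "U", step = 1, drop_orphans = TRUE,
                           stop_min_n = 20, stop_min_informative = 2,
                           stop_min_events = 1)
  expect_true(all(traj$n_remaining[-1] %% 2 == 0))
})

test_that("null scenario trajectories show no systematic trend", {
  cfg <- scenario_config(n = 1500, alphaU = 0, betaU = 0, betaZ = log(2),
                         seed = 103, reps = 30)
  seeds <- child_seeds(cfg$seed, cfg$reps)
  slopes <- vapply(seq_len(cfg$reps), function(r) {
    set.seed(seeds[r])
    matched <- match_cohort(simulate_cohort(cfg, seed = NA), "X")
    traj <- dynamic_landmark(matched, omitted = "U", step = 0.02,
                             stop_fraction = 0.45)
    detect_shift(traj)$slope
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes)), 2 * mc_se)
})
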