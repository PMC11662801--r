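# Small in-code fixtures shared across test files.

# Minimal valid cohort with one continuous covariate.
toy_cohort <- function(n = 8) {
  co <- tibble::tibble(
    id = seq_len(n),
    treatment = rep(c(1L, 0L), length.out = n),
    time = seq(1, n) + 0.5,
    event = rep(c(1L, 0L), each = ceiling(n / 2))[seq_len(n)],
    age = seq(50, by = 2, length.out = n)
  )
  attr(co, "covariate_spec") <- covariate_spec("age", "continuous")
  co
}

# 1:1 matched-pair cohort with a informative pairs won by the treated member
# failing first and b won by the control failing first; distinct times.
pair_cohort <- function(a, b, n_uninformative = 0) {
  n_pairs <- a + b + n_uninformative
  # interleave a- and b-pairs in follow-up order so sequential deletion does
  # not exhaust one direction first
  kinds <- c(c(rep("a", a), rep("b", b))[order(c(seq_len(a) / (a + 1),
                                                 seq_len(b) / (b + 1)))],
             rep("u", n_uninformative))
  rows <- list()
  tt <- 1
  for (j in seq_len(n_pairs)) {
    if (kinds[j] == "a") {           # treated fails first
      t_trt <- tt; e_trt <- 1L; t_ctl <- tt + 0.5; e_ctl <- 1L
    } else if (kinds[j] == "b") {    # control fails first
      t_ctl <- tt; e_ctl <- 1L; t_trt <- tt + 0.5; e_trt <- 1L
    } else {                # earlier time censored: uninformative
      t_trt <- tt; e_trt <- 0L; t_ctl <- tt + 0.5; e_ctl <- 1L
    }
    rows[[j]] <- tibble::tibble(
      id = c(2L * j - 1L, 2L * j), treatment = c(1L, 0L),
      time = c(t_trt, t_ctl), event = c(e_trt, e_ctl),
      stratum = c(j, j)
    )
    tt <- tt + 1
  }
  dplyr::bind_rows(rows)
}

# Synthetic landmark trajectory for exercising the diagnostics in isolation.
make_trajectory <- function(log_hr, ssq, n0 = 1000, se0 = 0.1, k = 1) {
  n_steps <- length(log_hr)
  m <- floor(n0 / (n_steps + 1))
  steps <- tibble::tibble(
    step = seq_len(n_steps) - 1L,
    landmark_time = seq(0, by = 0.1, length.out = n_steps),
    n_remaining = n0 - (seq_len(n_steps) - 1L) * m,
    events_remaining = n0 - (seq_len(n_steps) - 1L) * m,
    log_hr = log_hr, se = se0, ci_low = log_hr - 2 * se0,
    ci_high = log_hr + 2 * se0, converged = TRUE,
    informative_strata = NA_integer_,
    ssq_omitted = ssq, ssq_included = NA_real_,
    balance = replicate(n_steps, tibble::tibble(), simplify = FALSE)
  )
  structure(steps, class = c("landmark_trajectory", class(steps)),
            termination_reason = "min_size_reached", n0 = n0, m = m,
            k_omitted = k, estimator = "pair_stratified", omitted = "U",
            conf_level = 0.95)
}

# Printed group summaries (weight, euroSCORE II, age) from the published
# cardiac-surgery comparison used as arithmetic fixtures: list(treated = TA-
# TAVI, control = MIC-AVR), each (mean, sd, n).
surgical_summaries <- list(
  weight = list(a = c(73.66, 16.06, 607), b = c(81.04, 16.12, 1929), z = -9.86),
  euroscore2 = list(a = c(8.77, 8.87, 607), b = c(1.62, 1.44, 1929), z = 19.78),
  age_unmatched = list(a = c(81.28, 6.08, 607), b = c(67.85, 10.98, 1929), z = 38.24),
  age_13_15 = list(a = c(80.59, 6.07, 240), b = c(76.78, 6.42, 240), z = 6.68)
)
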