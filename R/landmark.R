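#' Sort a cohort by follow-up time
#'
#' Ascending in observed time; ties broken deterministically with events
#' before censored observations, then by subject id.
#'
#' @param cohort a cohort tibble.
#' @return The sorted cohort (attributes preserved).
#' @export
sort_by_followup <- function(cohort) {
  o <- order(cohort$time, -cohort$event, cohort$id)
  out <- cohort[o, ]
  attr(out, "covariate_spec") <- cohort_covariate_spec(cohort)
  out
}

#' Delete the earliest observations, regardless of event status
#'
#' Removes the first `m` subjects of a follow-up-sorted cohort irrespective of
#' whether they experienced the event or were censored. The landmark time is
#' the follow-up time of the latest deleted subject; every remaining subject
#' has follow-up at or beyond it, so subsequent fits condition on survival to
#' the landmark. Matched partners of deleted subjects are retained: their
#' strata become singletons that contribute nothing to a pair-stratified fit
#' but still count for balance.
#'
#' @param cohort a follow-up-sorted cohort.
#' @param m number of subjects to delete (`1 <= m < nrow(cohort)`).
#' @return List with `cohort` (remaining subjects) and `landmark_time`.
#' @export
delete_earliest <- function(cohort, m) {
  n <- nrow(cohort)
  if (m < 1) abort("m must be >= 1")
  if (m >= n) abort("m must be smaller than the current cohort size")
  landmark_time <- max(cohort$time[seq_len(m)])
  out <- cohort[-seq_len(m), ]
  attr(out, "covariate_spec") <- cohort_covariate_spec(cohort)
  list(cohort = out, landmark_time = landmark_time)
}

#' Dynamic Landmarking: sequential deletion, refitting, and balance tracking
#'
#' The core diagnostic loop. The cohort (typically the matched analysis set)
#' is sorted by follow-up time; step 0 records the treatment-only Cox fit and
#' the z-difference balance of the omitted covariates on the full set. Each
#' subsequent step deletes the earliest `step` observations regardless of
#' event status, advances time zero to the follow-up time of the latest
#' deleted subject (recorded for interpretation; partial-likelihood estimates
#' are invariant to the shift), refits the Cox model on the remaining
#' subjects, and recomputes the per-covariate z-differences and their SSQ
#' between the remaining treatment arms. Because high-baseline-risk subjects
#' tend to fail early, the trajectory of estimates across steps reveals
#' built-in selection bias (drift with rising SSQ of a still-balanced omitted
#' prognostic factor) and confounding bias (large SSQ already at step 0).
#'
#' The loop stops when the remaining data can no longer support a stable fit:
#' fewer than `stop_min_n` subjects, fewer than `stop_min_events` events in
#' either arm, fewer than `stop_min_informative` informative pairs
#' (stratified estimator), the remaining fraction dropping below
#' `stop_fraction`, or a fit failing to converge (recorded, then the loop
#' ends).
#'
#' @param cohort a cohort tibble; must carry `stratum` pair labels when
#'   `estimator = "pair_stratified"`.
#' @param omitted character vector of omitted covariates whose balance is
#'   tracked (>= 1; the method requires at least one omitted covariate).
#' @param step per-step deletion count: a fraction in (0,1) of the initial
#'   size, or an absolute count >= 1. Default 0.01 (about 100 steps).
#' @param estimator `"pair_stratified"` (default) or `"marginal"`.
#' @param spec optional [covariate_spec()] for the omitted covariates.
#' @param included optional covariates whose balance is additionally tracked
#'   (e.g. the PS-model covariates), reported as `ssq_included`.
#' @param stop_min_n,stop_min_events,stop_min_informative,stop_fraction stop
#'   thresholds (see Details).
#' @param drop_orphans if `TRUE`, matched partners of deleted subjects are
#'   removed as well (sensitivity analysis); default keeps them.
#' @param conf_level Wald CI level for each step's fit.
#' @return An object of class `landmark_trajectory`: tibble with one row per
#'   step (`step`, `landmark_time`, `n_remaining`, `events_remaining`,
#'   `log_hr`, `se`, `ci_low`, `ci_high`, `converged`, `ssq_omitted`,
#'   `ssq_included`, `balance` list-column of per-component z records) with
#'   attributes `termination_reason` (`"min_size_reached"`,
#'   `"non_convergence"` or `"exhausted"`), `n0`, `m`, `k_omitted`,
#'   `estimator`, `omitted`.
#' @examples
#' cfg <- scenario_config(n = 1500, betaU = log(3), seed = 11)
#' traj <- simulate_cohort(cfg) |>
#'   match_cohort("X") |>
#'   dynamic_landmark(omitted = "U", step = 0.05)
#' glance(traj)
#' @export
dynamic_landmark <- function(cohort, omitted, step = 0.01,
                             estimator = c("pair_stratified", "marginal"),
                             spec = NULL, included = NULL,
                             stop_min_n = 100, stop_min_events = 5,
                             stop_min_informative = 10, stop_fraction = 0,
                             drop_orphans = FALSE, conf_level = 0.95) {
  estimator <- match.arg(estimator)
  if (length(omitted) < 1) {
    abort("at least one covariate must be omitted and tracked for balance")
  }
  omit_spec <- spec_for(cohort, omitted, spec)
  incl_spec <- if (!is.null(included)) spec_for(cohort, included, spec)
  if (estimator == "pair_stratified" && !"stratum" %in% names(cohort)) {
    abort("pair_stratified estimator needs a 'stratum' column")
  }
  n0 <- nrow(cohort)
  m <- if (step < 1) max(1L, as.integer(round(step * n0))) else as.integer(step)
  data <- sort_by_followup(cohort)

  fit_fun <- if (estimator == "pair_stratified") {
    function(d) fit_cox_pair_stratified(d, conf_level)
  } else {
    function(d) fit_cox_marginal(d, conf_level)
  }

  steps <- list()
  landmark_time <- 0
  termination <- NULL
  i <- 0L
  repeat {
    fit <- tryCatch(fit_fun(data), error = function(e) NULL)
    bal <- balance_report(data, omitted, spec = omit_spec)
    bal_in <- if (!is.null(incl_spec)) balance_report(data, included, spec = incl_spec)
    steps[[i + 1L]] <- tibble::tibble(
      step = i, landmark_time = landmark_time,
      n_remaining = nrow(data), events_remaining = sum(data$event),
      log_hr = if (is.null(fit)) NA_real_ else fit$log_hr,
      se = if (is.null(fit)) NA_real_ else fit$se,
      ci_low = if (is.null(fit)) NA_real_ else fit$ci_low,
      ci_high = if (is.null(fit)) NA_real_ else fit$ci_high,
      converged = !is.null(fit) && fit$converged,
      informative_strata = if (is.null(fit)) NA_integer_ else fit$informative_strata,
      ssq_omitted = attr(bal, "ssq"),
      ssq_included = if (is.null(bal_in)) NA_real_ else attr(bal_in, "ssq"),
      balance = list(tibble::as_tibble(bal))
    )
    if (is.null(fit) || !fit$converged) { termination <- "non_convergence"; break }
    if (m >= nrow(data)) { termination <- "exhausted"; break }
    del <- delete_earliest(data, m)
    data <- del$cohort
    landmark_time <- del$landmark_time
    if (drop_orphans && "stratum" %in% names(data)) {
      keep <- stats::ave(rep(1, nrow(data)), data$stratum, FUN = sum) == 2
      spec_keep <- cohort_covariate_spec(data)
      data <- data[keep | is.na(data$stratum), ]
      attr(data, "covariate_spec") <- spec_keep
    }
    i <- i + 1L
    ev_t <- sum(data$event[data$treatment == 1])
    ev_c <- sum(data$event[data$treatment == 0])
    inf_ok <- TRUE
    if (estimator == "pair_stratified") {
      red <- pair_reduction(data)
      if (!is.null(red)) inf_ok <- (red$a + red$b) >= stop_min_informative
    }
    if (nrow(data) < stop_min_n || min(ev_t, ev_c) < stop_min_events ||
        !inf_ok || nrow(data) / n0 < stop_fraction ||
        length(unique(data$treatment)) < 2) {
      termination <- "min_size_reached"; break
    }
  }
  out <- dplyr::bind_rows(steps)
  structure(out,
            class = c("landmark_trajectory", class(out)),
            termination_reason = termination,
            n0 = n0, m = m, k_omitted = nrow(steps[[1]]$balance[[1]]),
            estimator = estimator, omitted = omitted,
            conf_level = conf_level)
}

#' @export
print.landmark_trajectory <- function(x, ...) {
  cat("Dynamic Landmarking trajectory: ", nrow(x), " steps (m = ",
      attr(x, "m"), " per step, ", attr(x, "estimator"), " estimator)\n",
      "termination: ", attr(x, "termination_reason"),
      "; omitted covariates: ", paste(attr(x, "omitted"), collapse = ", "),
      " (k = ", attr(x, "k_omitted"), ")\n", sep = "")
  print(tibble::as_tibble(x)[, c("step", "landmark_time", "n_remaining",
                                 "events_remaining", "log_hr", "se",
                                 "ssq_omitted", "converged")], ...)
  invisible(x)
}

#' @export
tidy.landmark_trajectory <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$balance <- NULL
  out
}

#' @export
glance.landmark_trajectory <- function(x, ...) {
  tibble::tibble(
    n_steps = nrow(x), n0 = attr(x, "n0"), m = attr(x, "m"),
    estimator = attr(x, "estimator"),
    termination_reason = attr(x, "termination_reason"),
    log_hr_step0 = x$log_hr[1], se_step0 = x$se[1],
    ssq_step0 = x$ssq_omitted[1], k_omitted = attr(x, "k_omitted")
  )
}

#' Plot a Dynamic Landmarking trajectory
#'
#' Dual-axis display: log hazard ratio (left axis) and SSQ of the omitted
#' covariates (right axis, rescaled) against the percentage of individuals
#' remaining, decreasing left to right.
#'
#' @param object a `landmark_trajectory`.
#' @param true_log_hr optional reference value drawn as a dashed line.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.landmark_trajectory <- function(object, true_log_hr = NULL, ...) {
  d <- tidy(object)
  d$pct_remaining <- 100 * d$n_remaining / attr(object, "n0")
  rng_hr <- range(c(d$log_hr, true_log_hr), na.rm = TRUE)
  if (diff(rng_hr) == 0) rng_hr <- rng_hr + c(-0.5, 0.5)
  rng_ssq <- range(d$ssq_omitted, na.rm = TRUE)
  if (diff(rng_ssq) == 0) rng_ssq <- rng_ssq + c(0, 1)
  scale_f <- diff(rng_hr) / diff(rng_ssq)
  d$ssq_scaled <- (d$ssq_omitted - rng_ssq[1]) * scale_f + rng_hr[1]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pct_remaining)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$log_hr), colour = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ssq_scaled), colour = "blue") +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_continuous(
      name = "log hazard ratio",
      sec.axis = ggplot2::sec_axis(~ (. - rng_hr[1]) / scale_f + rng_ssq[1],
                                   name = "SSQ of omitted covariates")
    ) +
    ggplot2::labs(x = "% of individuals remaining") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.title.y.left = ggplot2::element_text(colour = "red"),
      axis.title.y.right = ggplot2::element_text(colour = "blue")
    )
  if (!is.null(true_log_hr)) {
    p <- p + ggplot2::geom_hline(yintercept = true_log_hr,
                                 linetype = "dashed", colour = "black")
  }
  p
}

#' Write or read a trajectory as long-format CSV
#'
#' One row per landmark step with columns `step`, `landmark_time`,
#' `n_remaining`, `events_remaining`, `log_hr`, `se`, `ci_low`, `ci_high`,
#' `ssq_omitted`, `converged`, written at full precision.
#'
#' @param trajectory a nonempty `landmark_trajectory`.
#' @param path output/input CSV path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns a tibble of steps.
#' @export
write_trajectory <- function(trajectory, path) {
  if (!nrow(trajectory)) abort("trajectory is empty")
  cols <- c("step", "landmark_time", "n_remaining", "events_remaining",
            "log_hr", "se", "ci_low", "ci_high", "ssq_omitted", "converged")
  readr::write_csv(tibble::as_tibble(trajectory)[, cols], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
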