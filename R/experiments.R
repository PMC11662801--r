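#' Run a full simulation scenario: simulate, match, landmark, classify
#'
#' For each replicate: simulate a cohort from the scenario, estimate the
#' propensity score on X only (U stays omitted), form greedy 1:1 caliper
#' matches, run Dynamic Landmarking with the pair-stratified estimator
#' tracking U's balance, and classify the bias source. Replicates whose
#' matching or fitting fails are recorded and excluded from aggregates.
#'
#' @param config a [scenario_config()] (its `reps` and `seed` drive the run).
#' @param step,stop_fraction landmark settings passed to
#'   [dynamic_landmark()]; trajectories by default stop at 40% remaining since
#'   the diagnostics use only the first 50% of deletion.
#' @param caliper caliper multiplier for [ps_match()].
#' @param ps_covariates,omitted covariate roles (defaults `"X"` / `"U"`).
#' @param classify run the bias classifier per replicate (needs >= 10 steps).
#' @param grid_by spacing (in % remaining) of the common trajectory grid used
#'   to aggregate replicates with different stop points (linear interpolation
#'   between observed steps).
#' @return An object of class `scenario_result`: list with `config`,
#'   `replicates` (one row per successful replicate: `rep`, `matched_n`,
#'   `log_hr_step0`, `se_step0`, `ssq_step0`, `n_steps`, `label`,
#'   `shift_detected`), `grid`
#'   (per `pct_remaining`: mean and quartiles of log HR and SSQ), `tally`
#'   (classification counts), `n_failed`.
#' @export
run_scenario <- function(config, step = 0.01, stop_fraction = 0.4,
                         caliper = 0.2, ps_covariates = "X", omitted = "U",
                         classify = TRUE, grid_by = 1) {
  seeds <- child_seeds(config$seed, config$reps)
  one <- function(r) {
    set.seed(seeds[r])
    cohort <- simulate_cohort(config, seed = NA)
    matched <- match_cohort(cohort, ps_covariates, caliper = caliper)
    traj <- dynamic_landmark(matched, omitted = omitted, step = step,
                             stop_fraction = stop_fraction,
                             estimator = "pair_stratified")
    diag <- if (classify && nrow(traj) >= 10) classify_bias(traj)
    label <- if (is.null(diag)) NA_character_ else diag$label
    shift <- if (is.null(diag)) NA else diag$shift_detected
    list(
      summary = tibble::tibble(
        rep = r, seed = seeds[r], matched_n = nrow(matched),
        log_hr_step0 = traj$log_hr[1], se_step0 = traj$se[1],
        ssq_step0 = traj$ssq_omitted[1], n_steps = nrow(traj),
        termination = attr(traj, "termination_reason"), label = label,
        shift_detected = shift
      ),
      curve = tibble::tibble(
        rep = r,
        pct_remaining = 100 * traj$n_remaining / attr(traj, "n0"),
        log_hr = traj$log_hr, ssq = traj$ssq_omitted
      )
    )
  }
  results <- purrr::map(seq_len(config$reps), function(r) {
    tryCatch(one(r), error = function(e) e)
  })
  failed <- vapply(results, inherits, logical(1), "error")
  ok <- results[!failed]
  if (!length(ok)) abort("all replicates failed")
  replicates <- purrr::map_dfr(ok, "summary")
  curves <- purrr::map_dfr(ok, "curve")

  lo <- ceiling(max(tapply(curves$pct_remaining, curves$rep, min)))
  grid_pts <- seq(100, lo, by = -abs(grid_by))
  grid <- purrr::map_dfr(split(curves, curves$rep), function(d) {
    d <- d[order(-d$pct_remaining), ]
    tibble::tibble(
      rep = d$rep[1], pct_remaining = grid_pts,
      log_hr = approx(d$pct_remaining, d$log_hr, xout = grid_pts,
                      rule = 1)$y,
      ssq = approx(d$pct_remaining, d$ssq, xout = grid_pts, rule = 1)$y
    )
  })
  grid_summary <- grid |>
    dplyr::group_by(.data$pct_remaining) |>
    dplyr::summarise(
      log_hr_mean = mean(.data$log_hr, na.rm = TRUE),
      log_hr_q25 = quantile(.data$log_hr, 0.25, na.rm = TRUE),
      log_hr_q75 = quantile(.data$log_hr, 0.75, na.rm = TRUE),
      ssq_mean = mean(.data$ssq, na.rm = TRUE),
      ssq_q25 = quantile(.data$ssq, 0.25, na.rm = TRUE),
      ssq_q75 = quantile(.data$ssq, 0.75, na.rm = TRUE),
      n_reps = sum(is.finite(.data$log_hr)),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$pct_remaining))
  tally <- table(factor(replicates$label[!is.na(replicates$label)]))
  structure(
    list(config = config, replicates = replicates, grid = grid_summary,
         tally = tally, n_failed = sum(failed)),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario result:", nrow(x$replicates), "replicates (",
      x$n_failed, "failed ), role of U:", covariate_role(x$config), "\n")
  cat(sprintf("  mean matched n = %.1f; mean step-0 log HR = %.3f; mean step-0 SSQ = %.2f\n",
              mean(x$replicates$matched_n), mean(x$replicates$log_hr_step0),
              mean(x$replicates$ssq_step0)))
  if (length(x$tally)) {
    cat("  classification tally:\n")
    print(x$tally)
  }
  invisible(x)
}

#' @export
tidy.scenario_result <- function(x, ...) x$replicates

#' @export
glance.scenario_result <- function(x, ...) {
  tibble::tibble(
    role = covariate_role(x$config), reps = nrow(x$replicates),
    n_failed = x$n_failed,
    matched_n_mean = mean(x$replicates$matched_n),
    log_hr_step0_mean = mean(x$replicates$log_hr_step0),
    ssq_step0_mean = mean(x$replicates$ssq_step0),
    majority_label = if (length(x$tally)) names(which.max(x$tally)) else NA_character_
  )
}

#' Run a grid of scenarios
#'
#' Scenarios are run independently under their own seeds (seed-stable: the
#' result does not depend on execution order); a failing scenario is recorded
#' without aborting the rest.
#'
#' @param configs a list of [scenario_config()] objects.
#' @param ... passed to [run_scenario()].
#' @return A tibble with one row per scenario: `scenario` (index), the varied
#'   parameters, the [glance()] summary columns, and the full
#'   `scenario_result` in a `result` list-column (`NULL` where failed).
#' @export
run_grid <- function(configs, ...) {
  if (!length(configs)) abort("empty scenario list")
  purrr::imap_dfr(configs, function(cfg, i) {
    res <- tryCatch(run_scenario(cfg, ...), error = function(e) NULL)
    base <- tibble::tibble(
      scenario = i, alphaU = cfg$alphaU, betaU = cfg$betaU,
      betaZ = cfg$betaZ, rhoXU = cfg$rhoXU, censor_rate = cfg$censor_rate
    )
    if (is.null(res)) {
      dplyr::mutate(base, failed = TRUE, result = list(NULL))
    } else {
      dplyr::bind_cols(base, glance(res)) |>
        dplyr::mutate(failed = FALSE, result = list(res))
    }
  })
}

#' Plot mean trajectories of a scenario result
#'
#' @param object a `scenario_result`.
#' @param true_log_hr optional dashed reference line for the simulated
#'   conditional effect.
#' @param ... unused.
#' @return A ggplot object: mean log-HR (red) and SSQ (blue, right axis)
#'   curves with interquartile bands against % remaining.
#' @export
autoplot.scenario_result <- function(object, true_log_hr = NULL, ...) {
  g <- object$grid
  rng_hr <- range(c(g$log_hr_q25, g$log_hr_q75, true_log_hr), na.rm = TRUE)
  rng_ssq <- range(c(g$ssq_q25, g$ssq_q75), na.rm = TRUE)
  if (diff(rng_ssq) == 0) rng_ssq <- rng_ssq + c(0, 1)
  scale_f <- diff(rng_hr) / diff(rng_ssq)
  resc <- function(x) (x - rng_ssq[1]) * scale_f + rng_hr[1]
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$pct_remaining)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$log_hr_q25,
                                      ymax = .data$log_hr_q75),
                         fill = "red", alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = .data$log_hr_mean), colour = "red") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = resc(.data$ssq_q25),
                                      ymax = resc(.data$ssq_q75)),
                         fill = "blue", alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = resc(.data$ssq_mean)), colour = "blue") +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_continuous(
      name = "log hazard ratio",
      sec.axis = ggplot2::sec_axis(~ (. - rng_hr[1]) / scale_f + rng_ssq[1],
                                   name = "SSQ of omitted covariates")
    ) +
    ggplot2::labs(x = "% of individuals remaining") +
    ggplot2::theme_minimal()
  if (!is.null(true_log_hr)) {
    p <- p + ggplot2::geom_hline(yintercept = true_log_hr,
                                 linetype = "dashed")
  }
  p
}

#' Write a trajectory or scenario plot to file
#'
#' @param x a `landmark_trajectory` or `scenario_result`.
#' @param path output image path (extension selects the device, e.g. `.png`,
#'   `.pdf`).
#' @param true_log_hr optional reference line.
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
plot_trajectories <- function(x, path, true_log_hr = NULL,
                              width = 7, height = 4.5) {
  p <- autoplot(x, true_log_hr = true_log_hr)
  ggplot2::ggsave(path, p, width = width, height = height)
  invisible(path)
}
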