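#' Estimate the propensity score by logistic regression
#'
#' Maximum-likelihood logistic regression of treatment on the chosen
#' covariates (IRLS via [stats::glm()], relative tolerance 1e-8, up to 50
#' iterations). Complete or quasi-complete separation (non-convergence or any
#' |coefficient| > 15) and collinear designs are reported as errors: a
#' propensity model fitted on separated data would produce degenerate scores.
#'
#' @param cohort a cohort tibble.
#' @param covariates character vector of covariate column names for the PS
#'   model (>= 1).
#' @return The cohort with a `ps` column appended; the fitted coefficients are
#'   attached as attribute `"ps_coefficients"`.
#' @examples
#' cohort <- simulate_cohort(scenario_config(n = 500, seed = 7))
#' cohort <- estimate_ps(cohort, "X")
#' attr(cohort, "ps_coefficients")
#' @export
estimate_ps <- function(cohort, covariates) {
  if (length(covariates) < 1) abort("need at least one PS covariate")
  missing <- setdiff(covariates, names(cohort))
  if (length(missing)) {
    abort(paste0("PS covariate(s) not in cohort: ", paste(missing, collapse = ", ")))
  }
  if (length(unique(cohort$treatment)) < 2) {
    abort("both treatment arms must be nonempty")
  }
  f <- as.formula(paste("treatment ~", paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(
    glm(f, family = binomial(), data = cohort,
        control = list(epsilon = 1e-8, maxit = 50))
  )
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(paste0("collinear PS design: coefficient(s) not estimable (",
                 paste(names(cf)[is.na(cf)], collapse = ", "), ")"))
  }
  if (!fit$converged || any(abs(cf[-1]) > 15)) {
    abort("PS model did not converge (possible complete separation)")
  }
  out <- dplyr::mutate(cohort, ps = as.numeric(fitted(fit)))
  attr(out, "covariate_spec") <- cohort_covariate_spec(cohort)
  attr(out, "ps_coefficients") <- cf
  out
}

#' Greedy 1:1 nearest-neighbour caliper matching on the logit PS
#'
#' Treated subjects are processed in a seeded-random order (recorded for
#' replay). Each is paired with the nearest not-yet-used control by absolute
#' difference of logit propensity scores; a nearest neighbour farther than the
#' caliper leaves the treated subject unmatched. The caliper is
#' `caliper * SD(logit ps)` with the SD pooled over all subjects. Ties in
#' distance are broken towards the smaller control id. Matching is without
#' replacement; if there are more treated than controls, treated subjects
#' remain the cases.
#'
#' @param cohort a cohort tibble with a `ps` column (see [estimate_ps()]).
#' @param caliper caliper width as a multiple of the pooled SD of the logit
#'   PS (default 0.2).
#' @return An object of class `ps_match`: list with `pairs` (tibble `stratum`,
#'   `treated_id`, `control_id`, `distance`), `caliper_width`, `sd_logit_ps`,
#'   `unmatched_treated`, and `treated_order`.
#' @export
ps_match <- function(cohort, caliper = 0.2) {
  if (!"ps" %in% names(cohort)) abort("cohort has no 'ps' column; run estimate_ps() first")
  if (any(is.na(cohort$ps))) abort("missing propensity scores")
  lp <- qlogis(cohort$ps)
  sdl <- sd(lp)
  if (!is.finite(sdl) || sdl == 0) {
    abort("caliper undefined: logit propensity scores have zero spread")
  }
  width <- caliper * sdl
  treated <- which(cohort$treatment == 1)
  controls <- which(cohort$treatment == 0)
  if (!length(treated) || !length(controls)) abort("both arms must be nonempty")

  order_idx <- sample(length(treated))
  treated <- treated[order_idx]
  # controls kept sorted by logit PS (id as secondary key for tie-breaks)
  o <- order(lp[controls], cohort$id[controls])
  c_idx <- controls[o]
  c_lp <- lp[c_idx]
  pair_t <- integer(0); pair_c <- integer(0); pair_d <- numeric(0)
  unmatched <- integer(0)
  for (t in treated) {
    if (!length(c_lp)) { unmatched <- c(unmatched, t); next }
    j <- findInterval(lp[t], c_lp)
    cand <- unique(pmin(pmax(c(j, j + 1L), 1L), length(c_lp)))
    d <- abs(c_lp[cand] - lp[t])
    # nearest; exact distance tie -> smaller control id
    best <- cand[d == min(d)]
    k <- best[which.min(cohort$id[c_idx[best]])]
    if (abs(c_lp[k] - lp[t]) <= width) {
      pair_t <- c(pair_t, t); pair_c <- c(pair_c, c_idx[k])
      pair_d <- c(pair_d, abs(c_lp[k] - lp[t]))
      c_lp <- c_lp[-k]; c_idx <- c_idx[-k]
    } else {
      unmatched <- c(unmatched, t)
    }
  }
  pairs <- tibble::tibble(
    stratum = seq_along(pair_t),
    treated_id = cohort$id[pair_t],
    control_id = cohort$id[pair_c],
    distance = pair_d
  )
  structure(
    list(pairs = pairs, caliper_width = width, sd_logit_ps = sdl,
         unmatched_treated = cohort$id[unmatched],
         treated_order = cohort$id[treated]),
    class = "ps_match"
  )
}

#' @export
print.ps_match <- function(x, ...) {
  cat("1:1 greedy caliper match: ", nrow(x$pairs), " pairs, ",
      length(x$unmatched_treated), " unmatched treated\n",
      "caliper width ", signif(x$caliper_width, 4),
      " (SD of logit PS: ", signif(x$sd_logit_ps, 4), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.ps_match <- function(x, ...) x$pairs

#' @export
glance.ps_match <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs), n_unmatched_treated = length(x$unmatched_treated),
    caliper_width = x$caliper_width, sd_logit_ps = x$sd_logit_ps
  )
}

#' Restrict a cohort to its matched pairs
#'
#' @param cohort the cohort that was matched.
#' @param match a [ps_match()] result.
#' @return The matched subjects with a `stratum` column (pair label), ready for
#'   [fit_cox_pair_stratified()] and [dynamic_landmark()].
#' @export
matched_cohort <- function(cohort, match) {
  stopifnot(inherits(match, "ps_match"))
  long <- tidyr::pivot_longer(match$pairs, c("treated_id", "control_id"),
                              values_to = "id")
  out <- dplyr::inner_join(cohort, long[, c("stratum", "id")], by = "id")
  out <- dplyr::arrange(out, .data$stratum, dplyr::desc(.data$treatment))
  attr(out, "covariate_spec") <- cohort_covariate_spec(cohort)
  out
}

#' Propensity-score match a cohort in one call
#'
#' Convenience pipeline: [estimate_ps()] on `ps_covariates`, [ps_match()],
#' [matched_cohort()].
#'
#' @inheritParams estimate_ps
#' @inheritParams ps_match
#' @param ps_covariates covariates for the PS model.
#' @return The matched cohort; the `ps_match` object is attached as attribute
#'   `"match"`.
#' @export
match_cohort <- function(cohort, ps_covariates, caliper = 0.2) {
  withps <- estimate_ps(cohort, ps_covariates)
  m <- ps_match(withps, caliper = caliper)
  out <- matched_cohort(withps, m)
  attr(out, "match") <- m
  out
}
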