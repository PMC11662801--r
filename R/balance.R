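#' z-differences: standardized between-group covariate differences
#'
#' Unlike the standardized mean difference, a z-difference standardizes the
#' between-group difference by the standard error of that difference, so under
#' balance each z is approximately standard normal and the sum of squared
#' z-differences over k independent components is approximately chi-squared
#' with k degrees of freedom. The sign convention throughout is
#' (treated - control).
#'
#' `z_continuous()` is the Welch-type statistic
#' `(mean_a - mean_b) / sqrt(var_a/n_a + var_b/n_b)`; `z_binary()` is the
#' analogous two-proportion statistic. `z_ordinal()` standardizes the
#' Wilcoxon rank-sum (mid-ranks for ties, tie-corrected variance) on the
#' ordered levels and contributes one degree of freedom. `z_nominal()` returns
#' one indicator z per non-reference level (reference = first declared level),
#' contributing `length(levels) - 1` degrees of freedom.
#'
#' @param mean_a,var_a,n_a,mean_b,var_b,n_b group summaries (a = treated,
#'   b = control); variances are unbiased sample variances (divisor n - 1).
#' @return A single signed z (a numeric vector for `z_nominal()`).
#' @examples
#' # printed group summaries, weight in an unmatched surgical cohort:
#' z_continuous(73.66, 16.06^2, 607, 81.04, 16.12^2, 1929)  # approx -9.86
#' @export
z_continuous <- function(mean_a, var_a, n_a, mean_b, var_b, n_b) {
  if (n_a < 2 || n_b < 2) abort("need n >= 2 in each group")
  if (var_a < 0 || var_b < 0) abort("variances must be >= 0")
  den <- sqrt(var_a / n_a + var_b / n_b)
  if (den == 0) abort("zero denominator: both groups have zero variance")
  (mean_a - mean_b) / den
}

#' @rdname z_continuous
#' @param p_a,p_b group proportions in \[0, 1\].
#' @export
z_binary <- function(p_a, n_a, p_b, n_b) {
  if (any(c(p_a, p_b) < 0 | c(p_a, p_b) > 1)) abort("proportions must lie in [0,1]")
  if (n_a < 1 || n_b < 1) abort("need n >= 1 in each group")
  den <- sqrt(p_a * (1 - p_a) / n_a + p_b * (1 - p_b) / n_b)
  if (den == 0) abort("zero denominator: both proportions are degenerate (0 or 1)")
  (p_a - p_b) / den
}

#' @rdname z_continuous
#' @param counts_a,counts_b per-level counts (same ordered levels in both
#'   groups; names optional).
#' @export
z_ordinal <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b) || length(counts_a) < 2) {
    abort("need counts over the same >= 2 ordered levels in both groups")
  }
  n_a <- sum(counts_a); n_b <- sum(counts_b)
  if (n_a == 0 || n_b == 0) abort("both groups must be nonempty")
  tot <- counts_a + counts_b
  if (sum(tot > 0) < 2) abort("only one level occupied: ordinal z undefined")
  N <- n_a + n_b
  # mid-ranks per level
  upper <- cumsum(tot)
  midrank <- upper - (tot - 1) / 2
  W <- sum(counts_a * midrank)
  EW <- n_a * (N + 1) / 2
  sumr2 <- sum(tot * midrank^2)
  VW <- n_a * n_b / (N * (N - 1)) * (sumr2 - N * (N + 1)^2 / 4)
  if (VW <= 0) abort("degenerate rank variance")
  (W - EW) / sqrt(VW)
}

#' @rdname z_continuous
#' @export
z_nominal <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b) || length(counts_a) < 2) {
    abort("need counts over the same >= 2 levels in both groups")
  }
  n_a <- sum(counts_a); n_b <- sum(counts_b)
  if (n_a == 0 || n_b == 0) abort("both groups must be nonempty")
  vapply(seq_along(counts_a)[-1], function(l) {
    z_binary(counts_a[l] / n_a, n_a, counts_b[l] / n_b, n_b)
  }, numeric(1))
}

z_components <- function(x_t, x_c, kind, levels = NULL, name = "") {
  rec <- function(component, z) {
    tibble::tibble(name = name, kind = kind, component = component, z = z)
  }
  if (kind == "continuous") {
    v_t <- var(x_t); v_c <- var(x_c)
    if ((v_t + v_c) == 0) {
      if (mean(x_t) == mean(x_c)) return(rec(name, NA_real_))
      abort(paste0("covariate '", name, "' is constant at different values in the two arms"))
    }
    rec(name, z_continuous(mean(x_t), v_t, length(x_t),
                           mean(x_c), v_c, length(x_c)))
  } else if (kind == "binary") {
    p_t <- mean(x_t); p_c <- mean(x_c)
    if (p_t %in% c(0, 1) && p_c %in% c(0, 1)) {
      if (p_t == p_c) return(rec(name, NA_real_))
      abort(paste0("binary covariate '", name, "' is degenerate at different values"))
    }
    rec(name, z_binary(p_t, length(x_t), p_c, length(x_c)))
  } else {
    lv <- levels %||% levels(x_t) %||% sort(unique(c(x_t, x_c)))
    ct <- table(factor(x_t, levels = lv))
    cc <- table(factor(x_c, levels = lv))
    if (kind == "ordinal") {
      rec(name, z_ordinal(as.numeric(ct), as.numeric(cc)))
    } else {
      zs <- z_nominal(as.numeric(ct), as.numeric(cc))
      rec(paste0(name, ":", lv[-1]), zs)
    }
  }
}

#' Covariate balance between treatment arms: z-differences and SSQ
#'
#' Computes the per-covariate z-differences between the treated and control
#' arms of a cohort and aggregates them into the global balance statistic
#' `SSQ = sum(z^2)` over all components. Under balance (and approximately
#' independent covariates) SSQ follows a chi-squared distribution with
#' expectation k, where k is the total degrees of freedom (1 per continuous,
#' binary or ordinal covariate; number of levels - 1 per nominal covariate).
#' A standardized-mean-difference column is included for convenience on
#' continuous and binary covariates.
#'
#' A covariate degenerate (zero variance) in *both* arms at the same value is
#' recorded with `z = NA` (it contributes 0 to SSQ but its df is counted);
#' degeneracy at different values is an error.
#'
#' @param cohort a cohort tibble with both arms nonempty.
#' @param covariates names of the covariates to assess.
#' @param spec a [covariate_spec()]; defaults to the one attached to the
#'   cohort.
#' @return An object of class `balance_report`: tibble of components
#'   (`name`, `kind`, `component`, `z`, `smd`) with attributes `ssq`, `k`,
#'   `n_treated`, `n_control`.
#' @export
balance_report <- function(cohort, covariates, spec = NULL) {
  spec <- spec_for(cohort, covariates, spec)
  t_rows <- cohort$treatment == 1
  if (!any(t_rows) || all(t_rows)) abort("both arms must be nonempty")
  recs <- purrr::pmap(
    list(spec$name, spec$kind, spec$levels),
    function(nm, kd, lv) {
      x <- cohort[[nm]]
      out <- z_components(x[t_rows], x[!t_rows], kd, lv, nm)
      out$smd <- if (kd %in% c("continuous", "binary")) {
        x_t <- as.numeric(x[t_rows]); x_c <- as.numeric(x[!t_rows])
        den <- sqrt((var(x_t) + var(x_c)) / 2)
        if (is.na(den) || den == 0) NA_real_ else (mean(x_t) - mean(x_c)) / den
      } else NA_real_
      out
    }
  )
  recs <- dplyr::bind_rows(recs)
  out <- structure(recs, class = c("balance_report", class(recs)))
  attr(out, "ssq") <- sum(recs$z^2, na.rm = TRUE)
  attr(out, "k") <- nrow(recs)
  attr(out, "n_treated") <- sum(t_rows)
  attr(out, "n_control") <- sum(!t_rows)
  out
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Balance report: SSQ =", signif(attr(x, "ssq"), 5),
      "on k =", attr(x, "k"), "df",
      sprintf("(chi-square upper tail p = %.3g)\n",
              pchisq(attr(x, "ssq"), attr(x, "k"), lower.tail = FALSE)))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @export
tidy.balance_report <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.balance_report <- function(x, ...) {
  ssq <- attr(x, "ssq"); k <- attr(x, "k")
  tibble::tibble(
    ssq = ssq, k = k,
    p_value = pchisq(ssq, k, lower.tail = FALSE),
    n_treated = attr(x, "n_treated"), n_control = attr(x, "n_control")
  )
}
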