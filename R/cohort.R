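#' Validate a subject-level cohort table
#'
#' A cohort is an ordinary tibble with one row per subject and columns
#' `id` (unique), `treatment` (0/1), `time` (follow-up, strictly positive),
#' `event` (1 = event observed, 0 = censored; no other coding is accepted),
#' any number of covariate columns, and optionally `ps` (propensity score in
#' (0,1)) and `stratum` (matched-pair label; every label must occur exactly
#' twice with discordant treatment).
#'
#' @param cohort a data frame.
#' @param spec optional [covariate_spec()]; when supplied, every declared
#'   covariate must be present and conform to its kind.
#' @return The validated cohort, invisibly as a tibble.
#' @export
validate_cohort <- function(cohort, spec = NULL) {
  cohort <- tibble::as_tibble(cohort)
  for (col in c("id", "treatment", "time", "event")) {
    if (!col %in% names(cohort)) abort(paste0("missing required column '", col, "'"))
  }
  if (anyDuplicated(cohort$id)) abort("column 'id' must be unique")
  check_col <- function(x, col) {
    bad <- which(is.na(x))
    if (length(bad)) abort(paste0("missing values in '", col, "' (row ",
                                  bad[1], ")"))
  }
  check_col(cohort$treatment, "treatment")
  check_col(cohort$time, "time")
  check_col(cohort$event, "event")
  bad <- which(!cohort$treatment %in% c(0, 1))
  if (length(bad)) abort(paste0("'treatment' must be 0/1 (row ", bad[1], ")"))
  bad <- which(!cohort$event %in% c(0, 1))
  if (length(bad)) abort(paste0("'event' must be 0/1 (row ", bad[1], ")"))
  bad <- which(!(cohort$time > 0))
  if (length(bad)) abort(paste0("'time' must be strictly positive (row ",
                                bad[1], ")"))
  if (all(cohort$treatment == 1) || all(cohort$treatment == 0)) {
    warn("cohort has a single treatment arm")
  }
  if ("ps" %in% names(cohort)) {
    bad <- which(!is.na(cohort$ps) & !(cohort$ps > 0 & cohort$ps < 1))
    if (length(bad)) abort(paste0("'ps' must lie in (0,1) (row ", bad[1], ")"))
  }
  if ("stratum" %in% names(cohort)) {
    st <- cohort[!is.na(cohort$stratum), ]
    counts <- table(st$stratum)
    if (any(counts != 2)) {
      abort(paste0("stratum '", names(counts)[counts != 2][1],
                   "' does not contain exactly 2 subjects"))
    }
    disc <- tapply(st$treatment, st$stratum, function(z) sum(z) == 1)
    if (!all(disc)) {
      abort(paste0("stratum '", names(disc)[!disc][1],
                   "' is not treatment-discordant"))
    }
  }
  if (!is.null(spec)) {
    missing <- setdiff(spec$name, names(cohort))
    if (length(missing)) {
      abort(paste0("declared covariate(s) absent from cohort: ",
                   paste(missing, collapse = ", ")))
    }
    for (i in seq_len(nrow(spec))) {
      nm <- spec$name[i]
      x <- cohort[[nm]]
      if (spec$kind[i] == "binary" && !all(x %in% c(0, 1) | is.na(x))) {
        abort(paste0("binary covariate '", nm, "' must be coded 0/1"))
      }
      if (spec$kind[i] %in% c("ordinal", "nominal")) {
        lv <- spec$levels[[i]]
        vals <- unique(as.character(x[!is.na(x)]))
        extra <- setdiff(vals, lv)
        if (length(extra)) {
          abort(paste0("covariate '", nm, "' has undeclared level(s): ",
                       paste(extra, collapse = ", ")))
        }
      }
    }
    attr(cohort, "covariate_spec") <- spec
  }
  invisible(cohort)
}

#' Read a cohort CSV with its covariate-type sidecar
#'
#' The CSV must carry header columns `id`, `treatment`, `time`, `event`, one
#' column per declared covariate, and optionally `ps` and `stratum`. Any
#' covariate column present in the CSV must be declared in the sidecar.
#' Ordinal covariates are mapped to ordered factors, nominal covariates to
#' factors, both with the declared level order.
#'
#' @param path cohort CSV path.
#' @param spec_path JSON covariate-type sidecar path (see
#'   [read_covariate_spec()]); alternatively pass a [covariate_spec()] via
#'   `spec`.
#' @param spec a [covariate_spec()], used instead of `spec_path`.
#' @return A validated cohort tibble with the spec attached.
#' @export
read_cohort <- function(path, spec_path = NULL, spec = NULL) {
  if (is.null(spec) && is.null(spec_path)) {
    abort("supply `spec_path` or `spec`: covariate types are never inferred")
  }
  if (is.null(spec)) spec <- read_covariate_spec(spec_path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  reserved <- c("id", "treatment", "time", "event", "ps", "stratum")
  undeclared <- setdiff(names(raw), c(reserved, spec$name))
  if (length(undeclared)) {
    abort(paste0("undeclared covariate column(s): ",
                 paste(undeclared, collapse = ", ")))
  }
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    if (!nm %in% names(raw)) next
    if (spec$kind[i] == "ordinal") {
      raw[[nm]] <- factor(as.character(raw[[nm]]), levels = spec$levels[[i]],
                          ordered = TRUE)
    } else if (spec$kind[i] == "nominal") {
      raw[[nm]] <- factor(as.character(raw[[nm]]), levels = spec$levels[[i]])
    }
  }
  cohort <- validate_cohort(raw, spec = spec)
  tibble::as_tibble(cohort)
}

#' Write a cohort CSV (and optionally its sidecar)
#'
#' @param cohort a validated cohort tibble.
#' @param path output CSV path.
#' @param spec_path optional path for the covariate-type JSON sidecar; when
#'   `NULL` only the CSV is written.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, spec_path = NULL) {
  out <- tibble::as_tibble(cohort)
  fct <- vapply(out, is.factor, logical(1))
  out[fct] <- lapply(out[fct], as.character)
  readr::write_csv(out, path, progress = FALSE)
  if (!is.null(spec_path)) {
    spec <- cohort_covariate_spec(cohort)
    if (is.null(spec)) abort("cohort carries no covariate spec to write")
    write_covariate_spec(spec, spec_path)
  }
  invisible(path)
}

#' Read an analysis configuration (YAML or JSON)
#'
#' Run configurations bundle the covariate roles (`ps_covariates`,
#' `omitted_covariates`), the estimator (`"marginal"` or `"pair_stratified"`),
#' the deletion step, caliper multiplier, confidence level and seed used by the
#' landmark pipeline. YAML and JSON are accepted interchangeably (sniffed from
#' the extension).
#'
#' @param path configuration file path (`.yaml`/`.yml` or `.json`).
#' @return A validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- list(
    ps_covariates = character(), omitted_covariates = character(),
    estimator = "pair_stratified", step = 0.01, caliper = 0.2,
    conf_level = 0.95, seed = 1L,
    stop_min_n = 100, stop_min_events = 5, stop_min_informative = 10
  )
  cfg <- utils::modifyList(defaults, cfg)
  if (length(intersect(cfg$ps_covariates, cfg$omitted_covariates))) {
    abort("ps_covariates and omitted_covariates must be disjoint")
  }
  if (!cfg$estimator %in% c("marginal", "pair_stratified")) {
    abort("estimator must be 'marginal' or 'pair_stratified'")
  }
  if (!(cfg$step >= 1 || (cfg$step > 0 && cfg$step < 1))) {
    abort("step must be >= 1 (count) or in (0,1) (fraction)")
  }
  structure(cfg, class = "run_config")
}
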