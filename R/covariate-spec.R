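#' Declare covariate types for balance computations
#'
#' The z-difference decomposition of the SSQ balance statistic depends on each
#' covariate's measurement scale: continuous and binary covariates contribute
#' one squared z each, an ordinal covariate contributes one rank-based z, and a
#' nominal covariate with L levels contributes L - 1 indicator z's. Types are
#' therefore declared explicitly (in code or in a JSON sidecar next to a cohort
#' CSV) rather than inferred from the data, because silently misreading an
#' ordinal covariate as nominal changes the degrees of freedom of the chi-square
#' reference.
#'
#' @param name character vector of covariate names.
#' @param kind character vector (recycled) drawn from `"continuous"`,
#'   `"binary"`, `"ordinal"`, `"nominal"`.
#' @param levels list of character vectors giving the ordered category labels
#'   for ordinal/nominal covariates; must be `NULL` entries for continuous and
#'   binary covariates.
#' @return A `covariate_spec` tibble with columns `name`, `kind`, `levels`.
#' @examples
#' covariate_spec(
#'   name   = c("age", "female", "nyha"),
#'   kind   = c("continuous", "binary", "ordinal"),
#'   levels = list(NULL, NULL, c("I", "II", "III", "IV"))
#' )
#' @export
covariate_spec <- function(name, kind, levels = NULL) {
  kinds <- c("continuous", "binary", "ordinal", "nominal")
  if (anyDuplicated(name)) {
    abort("covariate names must be unique")
  }
  kind <- rep_len(kind, length(name))
  if (!all(kind %in% kinds)) {
    abort(paste0("covariate kind must be one of: ", paste(kinds, collapse = ", ")))
  }
  if (is.null(levels)) levels <- vector("list", length(name))
  if (length(levels) != length(name)) {
    abort("`levels` must have one entry per covariate")
  }
  for (i in seq_along(name)) {
    lv <- levels[[i]]
    if (kind[i] %in% c("ordinal", "nominal")) {
      if (is.null(lv) || length(lv) < 2) {
        abort(paste0("covariate '", name[i], "' (", kind[i],
                     ") needs >= 2 declared levels"))
      }
      if (anyDuplicated(lv)) {
        abort(paste0("levels of covariate '", name[i], "' must be unique"))
      }
      levels[[i]] <- as.character(lv)
    } else if (!is.null(lv)) {
      abort(paste0("covariate '", name[i], "' (", kind[i],
                   ") must not declare levels"))
    }
  }
  out <- tibble::tibble(name = as.character(name), kind = kind, levels = levels)
  class(out) <- c("covariate_spec", class(out))
  out
}

#' Read or write a covariate-type sidecar (JSON)
#'
#' The sidecar is an array of objects with fields `name`, `kind` and, for
#' ordinal/nominal covariates, `levels` (ordered).
#'
#' @param path file path of the JSON sidecar.
#' @return `read_covariate_spec()` returns a [covariate_spec()];
#'   `write_covariate_spec()` returns `path` invisibly.
#' @export
read_covariate_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(raw) == 0) abort(paste0("empty covariate spec: ", path))
  covariate_spec(
    name = vapply(raw, function(x) x$name, character(1)),
    kind = vapply(raw, function(x) x$kind, character(1)),
    levels = lapply(raw, function(x) {
      if (is.null(x$levels)) NULL else as.character(unlist(x$levels))
    })
  )
}

#' @rdname read_covariate_spec
#' @param spec a [covariate_spec()].
#' @export
write_covariate_spec <- function(spec, path) {
  stopifnot(inherits(spec, "covariate_spec"))
  out <- lapply(seq_len(nrow(spec)), function(i) {
    x <- list(name = spec$name[i], kind = spec$kind[i])
    if (!is.null(spec$levels[[i]])) x$levels <- as.list(spec$levels[[i]])
    x
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Retrieve the covariate spec attached to a cohort
#'
#' @param cohort a cohort tibble (see [read_cohort()] or [simulate_cohort()]).
#' @return The attached [covariate_spec()], or `NULL` if none.
#' @export
cohort_covariate_spec <- function(cohort) {
  attr(cohort, "covariate_spec", exact = TRUE)
}

spec_for <- function(cohort, names, spec = NULL) {
  spec <- spec %||% cohort_covariate_spec(cohort)
  if (is.null(spec)) {
    abort("no covariate spec: attach one to the cohort or pass `spec`")
  }
  missing <- setdiff(names, spec$name)
  if (length(missing)) {
    abort(paste0("covariate(s) not declared in spec: ",
                 paste(missing, collapse = ", ")))
  }
  spec[match(names, spec$name), , drop = FALSE]
}
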