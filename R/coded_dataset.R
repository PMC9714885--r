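#' Construct a variable specification
#'
#' A variable spec describes one categorical (or derived-categorical)
#' analysis variable: its name, the ordered set of legal category labels,
#' and, for derived variables, the raw source column and the name of the
#' recoding rule that produced it.
#'
#' @param name Variable name (character scalar).
#' @param categories Ordered character vector of legal category labels;
#'   must be non-empty and unique. The order defines the coded order used
#'   for deterministic tie-breaking downstream.
#' @param kind `"categorical"` (taken as-is from the input) or
#'   `"derived-categorical"` (computed by a recoding rule).
#' @param source_column Name of the raw input column a derived variable was
#'   computed from, or `NA`.
#' @param coding_rule Name of the recoding rule applied, or `NA`.
#'
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, categories, kind = c("categorical", "derived-categorical"),
                          source_column = NA_character_, coding_rule = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  categories <- as.character(categories)
  if (length(categories) == 0L) {
    stop("variable '", name, "': categories must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(categories)) {
    stop("variable '", name, "': categories must be unique", call. = FALSE)
  }
  structure(
    list(name = name, kind = kind, categories = categories,
         source_column = source_column, coding_rule = coding_rule),
    class = "variable_spec"
  )
}

#' Construct a coded dataset
#'
#' The central container of the package: one row per child aged 0-59 months,
#' carrying the height-for-age z-score (`haz`), the survey sampling weight
#' (`weight`), geography (`division`, `district`, optionally `cluster_id`)
#' and any number of coded categorical covariates described by the codebook.
#'
#' @param data A data frame with at least columns `haz` (numeric, may be
#'   `NA`), `weight` (positive numeric), `division` and `district`
#'   (character).
#' @param codebook A list of [variable_spec()] objects describing the coded
#'   covariate columns present in `data`.
#' @param survey_label Free-text label for the survey round (e.g. a year).
#'
#' @return An object of class `coded_dataset` with elements `data`
#'   (a tibble), `codebook` and `survey_label`.
#' @export
coded_dataset <- function(data, codebook = list(), survey_label = NA_character_) {
  ds <- structure(
    list(data = tibble::as_tibble(data),
         codebook = codebook,
         survey_label = survey_label),
    class = "coded_dataset"
  )
  validate_coded_dataset(ds)
}

#' Validate a coded dataset
#'
#' Checks the container invariants: mandatory columns present, weights
#' strictly positive, `haz` finite where non-missing, and every value of a
#' codebook variable either a legal category or `NA`.
#'
#' @param ds A `coded_dataset`.
#' @return `ds`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_coded_dataset <- function(ds) {
  stopifnot(inherits(ds, "coded_dataset"))
  d <- ds$data
  for (col in c("haz", "weight", "division", "district")) {
    if (!col %in% names(d)) {
      stop("coded_dataset: mandatory column '", col, "' is missing", call. = FALSE)
    }
  }
  if (nrow(d) == 0L) stop("coded_dataset: no records", call. = FALSE)
  if (any(is.na(d$weight)) || any(d$weight <= 0)) {
    stop("coded_dataset: weights must be present and > 0", call. = FALSE)
  }
  bad_haz <- !is.na(d$haz) & !is.finite(d$haz)
  if (any(bad_haz)) stop("coded_dataset: non-finite haz values", call. = FALSE)
  for (vs in ds$codebook) {
    if (!vs$name %in% names(d)) {
      stop("coded_dataset: codebook variable '", vs$name,
           "' has no data column", call. = FALSE)
    }
    vals <- d[[vs$name]]
    bad <- !is.na(vals) & !(vals %in% vs$categories)
    if (any(bad)) {
      stop("coded_dataset: variable '", vs$name, "' has ", sum(bad),
           " value(s) outside its categories (e.g. '",
           vals[bad][1L], "')", call. = FALSE)
    }
  }
  invisible(ds)
}

#' Names of the coded variables in a dataset's codebook
#' @param ds A `coded_dataset`.
#' @return Character vector of variable names, in codebook order.
#' @export
codebook_variables <- function(ds) {
  vapply(ds$codebook, function(vs) vs$name, character(1))
}

#' Look up the category labels of a codebook variable
#' @param ds A `coded_dataset`.
#' @param variable Variable name.
#' @return Ordered character vector of categories.
#' @export
variable_categories <- function(ds, variable) {
  for (vs in ds$codebook) if (vs$name == variable) return(vs$categories)
  stop("variable '", variable, "' not in codebook", call. = FALSE)
}

#' @export
print.coded_dataset <- function(x, ...) {
  cat("<coded_dataset>", if (!is.na(x$survey_label)) paste0("[", x$survey_label, "]"), "\n")
  cat("  records:  ", nrow(x$data), "\n", sep = "")
  cat("  divisions:", length(unique(x$data$division)), "\n")
  cat("  codebook: ", length(x$codebook), " variable(s): ",
      paste(codebook_variables(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of records in a coded dataset
#' @param ds A `coded_dataset`.
#' @return Integer record count.
#' @export
n_records <- function(ds) nrow(ds$data)

#' Restrict a dataset to complete cases on chosen variables
#'
#' Per-analysis listwise deletion: keeps only records with a non-missing
#' height-for-age z-score and non-missing values for every named variable.
#' Each analysis (screening run, polling run) calls this with exactly the
#' variables it uses, so every analysis retains its own maximal sample.
#'
#' @param ds A `coded_dataset`.
#' @param variables Character vector of codebook variable names (may be
#'   empty: then only the non-missing-HAZ restriction applies).
#' @param quiet Suppress the retained-fraction message.
#'
#' @return A `coded_dataset` containing the retained records.
#' @export
complete_cases <- function(ds, variables = character(), quiet = FALSE) {
  stopifnot(inherits(ds, "coded_dataset"))
  known <- union(codebook_variables(ds), names(ds$data))
  unknown <- setdiff(variables, known)
  if (length(unknown) > 0L) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  d <- ds$data
  keep <- !is.na(d$haz)
  for (v in variables) keep <- keep & !is.na(d[[v]])
  if (!any(keep)) {
    n_miss <- vapply(variables, function(v) sum(is.na(d[[v]])), integer(1))
    worst <- if (length(variables) > 0L) variables[which.max(n_miss)] else "haz"
    stop("no complete cases remain; most missingness in '", worst, "'", call. = FALSE)
  }
  if (!quiet) {
    message(sprintf("complete_cases: retained %d/%d records (%.1f%%)",
                    sum(keep), nrow(d), 100 * mean(keep)))
  }
  out <- ds
  out$data <- d[keep, , drop = FALSE]
  out
}
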