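# Recoding rules for the standard analysis variables. Cut points:
#   child age:        > 12 months => ">1y" (exactly 12 months codes "<=1y")
#   education years:  0 => none, 1-5 => primary, >= 6 => secondary+
#   mother BMI:       < 18.5 underweight, [18.5, 25) normal, >= 25 overweight+
#   mother height:    < 145 cm vs >= 145 cm
#   mother age at birth: < 20, 20-34, >= 35 (years)

.code_age_over_1y <- function(x) {
  x <- suppressWarnings(as.numeric(x))
  out <- ifelse(x > 12, ">1y", "<=1y")
  out[is.na(x) | x < 0] <- NA_character_
  out
}

.code_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% c("male", "m", "1", "boy")] <- "male"
  out[key %in% c("female", "f", "2", "girl")] <- "female"
  out
}

.code_education <- function(x) {
  y <- suppressWarnings(as.numeric(x))
  out <- rep(NA_character_, length(y))
  out[!is.na(y) & y == 0] <- "none"
  out[!is.na(y) & y > 0 & y < 6] <- "primary"
  out[!is.na(y) & y >= 6] <- "secondary+"
  out[!is.na(y) & y < 0] <- NA_character_
  out
}

.code_bmi <- function(x) {
  y <- suppressWarnings(as.numeric(x))
  out <- rep(NA_character_, length(y))
  ok <- !is.na(y) & y > 0
  out[ok & y < 18.5] <- "underweight"
  out[ok & y >= 18.5 & y < 25] <- "normal"
  out[ok & y >= 25] <- "overweight+"
  out
}

.code_height <- function(x) {
  y <- suppressWarnings(as.numeric(x))
  out <- rep(NA_character_, length(y))
  ok <- !is.na(y) & y > 0
  out[ok & y < 145] <- "<145cm"
  out[ok & y >= 145] <- ">=145cm"
  out
}

.code_mother_age <- function(x) {
  y <- suppressWarnings(as.numeric(x))
  out <- rep(NA_character_, length(y))
  ok <- !is.na(y) & y > 0
  out[ok & y < 20] <- "<20"
  out[ok & y >= 20 & y < 35] <- "20-34"
  out[ok & y >= 35] <- ">=35"
  out
}

.code_delivery <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% c("home", "1")] <- "home"
  out[key %in% c("facility", "institution", "institutional", "2")] <- "facility"
  out
}

.wealth_labels <- c("poorest", "poorer", "middle", "richer", "richest")

.code_wealth <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% .wealth_labels] <- key[key %in% .wealth_labels]
  idx <- match(key, as.character(1:5))
  out[!is.na(idx)] <- .wealth_labels[idx[!is.na(idx)]]
  out
}

.code_residence <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% c("urban", "1")] <- "urban"
  out[key %in% c("rural", "2")] <- "rural"
  out
}

.code_under5 <- function(x) {
  y <- suppressWarnings(as.numeric(x))
  out <- rep(NA_character_, length(y))
  ok <- !is.na(y) & y >= 0
  out[ok & y == 0] <- "none"
  out[ok & y == 1] <- "one"
  out[ok & y >= 2] <- "two+"
  out
}

# name, source canonical column, coder, ordered categories
.standard_codings <- function() {
  list(
    list(name = "child_sex", source = "sex", rule = "sex",
         fn = .code_sex, categories = c("male", "female")),
    list(name = "child_age_over_1y", source = "age_months", rule = "age_over_1y",
         fn = .code_age_over_1y, categories = c("<=1y", ">1y")),
    list(name = "mother_education", source = "mother_edu_years", rule = "education_years",
         fn = .code_education, categories = c("none", "primary", "secondary+")),
    list(name = "father_education", source = "father_edu_years", rule = "education_years",
         fn = .code_education, categories = c("none", "primary", "secondary+")),
    list(name = "mother_bmi", source = "mother_bmi_kgm2", rule = "who_bmi",
         fn = .code_bmi, categories = c("underweight", "normal", "overweight+")),
    list(name = "mother_height", source = "mother_height_cm", rule = "height_145",
         fn = .code_height, categories = c("<145cm", ">=145cm")),
    list(name = "mother_age_at_birth", source = "mother_age_at_birth_years", rule = "mother_age",
         fn = .code_mother_age, categories = c("<20", "20-34", ">=35")),
    list(name = "delivery_place", source = "delivery_place_code", rule = "delivery",
         fn = .code_delivery, categories = c("home", "facility")),
    list(name = "wealth_quintile", source = "wealth_index", rule = "wealth",
         fn = .code_wealth, categories = .wealth_labels),
    list(name = "wealth_quintile_ru", source = "wealth_index_ru", rule = "wealth",
         fn = .code_wealth, categories = .wealth_labels),
    list(name = "residence", source = "residence_code", rule = "residence",
         fn = .code_residence, categories = c("urban", "rural")),
    list(name = "other_under5", source = "other_under5_count", rule = "under5_count",
         fn = .code_under5, categories = c("none", "one", "two+"))
  )
}

.derived_variable_names <- function() {
  vapply(.standard_codings(), function(cd) cd$name, character(1))
}

#' Apply the standard categorical codings
#'
#' Derives the analysis covariates from their raw columns where present:
#' child sex and age band (cut at 12 months), mother's and father's
#' education (`none` / `primary` / `secondary+`, cuts at 0 and 6 completed
#' years), mother's BMI (WHO cuts 18.5 and 25.0 kg/m^2), mother's height
#' (145 cm), mother's age at the child's birth (20 and 35 years), place of
#' delivery (`home` / `facility`), wealth quintile (national and optional
#' rural/urban-specific coding), residence, and the count of other
#' under-fives in the household (`none` / `one` / `two+`).
#'
#' Columns that already hold legal category labels pass through untouched
#' (so the function is idempotent). Raw values no rule can map are coded
#' missing and counted in a single warning.
#'
#' @param ds A `coded_dataset` from [load_children_table()] or
#'   [generate_children()].
#' @return A `coded_dataset` with the derived columns added and the
#'   codebook extended to describe them.
#' @export
apply_standard_codings <- function(ds) {
  stopifnot(inherits(ds, "coded_dataset"))
  d <- ds$data
  codebook <- ds$codebook
  have <- codebook_variables(ds)
  unmapped <- integer(0)

  for (cd in .standard_codings()) {
    if (cd$name %in% have) next  # already coded and in the codebook
    if (cd$name %in% names(d)) {
      # pre-coded column without a codebook entry: validate, don't recode
      vals <- as.character(d[[cd$name]])
      bad <- !is.na(vals) & !(vals %in% cd$categories)
      if (any(bad)) {
        stop("column '", cd$name, "' holds values outside its categories (e.g. '",
             vals[bad][1L], "'); map the raw column '", cd$source,
             "' instead", call. = FALSE)
      }
      d[[cd$name]] <- vals
    } else if (cd$source %in% names(d)) {
      raw <- d[[cd$source]]
      coded <- cd$fn(raw)
      n_bad <- sum(!is.na(raw) & is.na(coded))
      if (n_bad > 0L) unmapped[cd$name] <- n_bad
      d[[cd$name]] <- coded
    } else {
      next  # neither coded nor raw column present: variable not available
    }
    codebook <- c(codebook, list(variable_spec(
      name = cd$name, categories = cd$categories,
      kind = "derived-categorical",
      source_column = if (cd$source %in% names(ds$data)) cd$source else NA_character_,
      coding_rule = cd$rule
    )))
  }

  if (length(unmapped) > 0L) {
    warning("apply_standard_codings: unmappable raw values set to missing: ",
            paste(sprintf("%s (%d)", names(unmapped), unmapped), collapse = ", "),
            call. = FALSE)
  }
  out <- ds
  out$data <- d
  out$codebook <- codebook
  validate_coded_dataset(out)
  out
}
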