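#' Classify stunting severity from height-for-age z-scores
#'
#' WHO classification: severe stunting below -3 SD, moderate between -3 and
#' -2 SD, not stunted at -2 SD or above. Both thresholds are strict
#' (`haz < -2`, `haz < -3`), so a score of exactly -2 or -3 falls in the
#' less severe class. Total stunting is the union of severe and moderate.
#'
#' @param haz Numeric vector of height-for-age z-scores; `NA` allowed.
#' @return Character vector with values `"severe"`, `"moderate"`,
#'   `"not_stunted"`, or `NA` where `haz` is missing or non-finite.
#' @export
#' @examples
#' classify_stunting(c(-3.2, -2.5, -2.0, 0.4))
classify_stunting <- function(haz) {
  haz <- as.numeric(haz)
  out <- rep(NA_character_, length(haz))
  ok <- is.finite(haz)
  out[ok & haz < -3] <- "severe"
  out[ok & haz >= -3 & haz < -2] <- "moderate"
  out[ok & haz >= -2] <- "not_stunted"
  out
}

# 0/1 outcome indicator for a stunting outcome definition; NA where haz is.
.stunting_indicator <- function(haz, outcome = c("total", "severe", "moderate")) {
  outcome <- match.arg(outcome)
  cls <- classify_stunting(haz)
  ind <- switch(outcome,
    total = as.integer(cls %in% c("severe", "moderate")),
    severe = as.integer(cls == "severe"),
    moderate = as.integer(cls == "moderate")
  )
  ind[is.na(cls)] <- NA_integer_
  ind
}

#' Weighted stunting prevalence, overall or by stratum
#'
#' Prevalence in a stratum is the weight share of children with the chosen
#' outcome: `sum(w * 1[outcome]) / sum(w)` over records with non-missing
#' HAZ. Records with missing HAZ are dropped with a message. The
#' unweighted count is reported alongside so small strata are auditable.
#'
#' @param ds A `coded_dataset`.
#' @param outcome `"total"` (HAZ < -2), `"severe"` (HAZ < -3) or
#'   `"moderate"` (-3 <= HAZ < -2).
#' @param by Name of a stratifier column (e.g. `"division"`,
#'   `"district"`), or `NULL` for a single overall row.
#'
#' @return A tibble with columns `stratum`, `outcome`, `n` (unweighted
#'   count) and `prevalence` (weighted proportion in `[0, 1]`), one row per
#'   observed stratum.
#' @export
weighted_prevalence <- function(ds, outcome = c("total", "severe", "moderate"),
                                by = NULL) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(ds, "coded_dataset"))
  d <- ds$data
  drop <- is.na(d$haz)
  if (any(drop)) {
    message(sprintf("weighted_prevalence: dropped %d record(s) with missing HAZ",
                    sum(drop)))
    d <- d[!drop, , drop = FALSE]
  }
  ind <- .stunting_indicator(d$haz, outcome)
  if (is.null(by)) {
    strata <- rep("all", nrow(d))
  } else {
    if (!by %in% names(d)) stop("stratifier '", by, "' not found", call. = FALSE)
    strata <- as.character(d[[by]])
    miss <- is.na(strata)
    if (any(miss)) {
      warning("weighted_prevalence: ", sum(miss),
              " record(s) with missing stratum omitted", call. = FALSE)
      d <- d[!miss, , drop = FALSE]
      ind <- ind[!miss]
      strata <- strata[!miss]
    }
  }
  labs <- sort(unique(strata))
  rows <- lapply(labs, function(s) {
    sel <- strata == s
    tibble::tibble(stratum = s, outcome = outcome, n = sum(sel),
                   prevalence = sum(d$weight[sel] * ind[sel]) / sum(d$weight[sel]))
  })
  do.call(rbind, rows)
}

#' Band district prevalences for choropleth-style reporting
#'
#' Assigns each stratum's prevalence to one of four bands:
#' `<=30%` for prevalence in `[0, 0.30]`, `30-40%` for `(0.30, 0.40)`,
#' `40-50%` for `[0.40, 0.50)` and `>=50%` for `[0.50, 1]`. The outer
#' bands are inclusive at 0.30 and 0.50; the interior boundaries are
#' half-open so that every prevalence falls in exactly one band.
#'
#' @param pt A prevalence table from [weighted_prevalence()] stratified by
#'   district (any stratifier is accepted; the stratum column is carried
#'   through).
#' @return A tibble with columns `district`, `n`, `prevalence`, `band`.
#' @export
district_banding <- function(pt) {
  stopifnot(is.data.frame(pt), all(c("stratum", "prevalence") %in% names(pt)))
  p <- pt$prevalence
  band <- ifelse(p <= 0.30, "<=30%",
          ifelse(p < 0.40, "30-40%",
          ifelse(p < 0.50, "40-50%", ">=50%")))
  tibble::tibble(district = pt$stratum, n = pt$n,
                 prevalence = p, band = band)
}
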