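#' Univariate screening of one covariate against stunting
#'
#' For each category of `variable`, reports the unweighted count and the
#' weighted stunting prevalence among complete cases on that variable, plus
#' one Pearson chi-square test of independence between the variable and the
#' binary stunting outcome. The test is computed on the weighted 2 x K
#' contingency table rescaled so its grand total equals the unweighted
#' sample size; with unit weights this is exactly the textbook Pearson
#' statistic, and the rescaling makes the statistic invariant to the
#' overall scale of the weights. No survey design-effect correction is
#' applied: the screening is a descriptive gate on candidate covariates,
#' not an inferential endpoint.
#'
#' @param ds A `coded_dataset` with codings applied.
#' @param variable Name of a codebook variable.
#' @param outcome Stunting outcome definition, as in
#'   [weighted_prevalence()].
#' @return A tibble with one row per observed category: `variable`,
#'   `category`, `n`, `prevalence`, and the test columns `statistic`, `df`,
#'   `p_value` repeated on every row (one test per variable). A variable
#'   with a single observed category gets `NA` test columns.
#' @export
screen_variable <- function(ds, variable, outcome = c("total", "severe", "moderate")) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(ds, "coded_dataset"))
  cats <- variable_categories(ds, variable)
  cc <- complete_cases(ds, variable, quiet = TRUE)
  d <- cc$data
  ind <- .stunting_indicator(d$haz, outcome)
  obs <- cats[cats %in% unique(d[[variable]])]

  n_k <- vapply(obs, function(k) sum(d[[variable]] == k), integer(1))
  prev_k <- vapply(obs, function(k) {
    sel <- d[[variable]] == k
    sum(d$weight[sel] * ind[sel]) / sum(d$weight[sel])
  }, numeric(1))

  stat <- df <- p <- NA_real_
  if (length(obs) >= 2L) {
    W <- vapply(obs, function(k) {
      sel <- d[[variable]] == k
      c(sum(d$weight[sel] * ind[sel]), sum(d$weight[sel] * (1 - ind[sel])))
    }, numeric(2))            # 2 x K: row 1 = outcome, row 2 = not
    Tm <- W * nrow(d) / sum(W)
    rs <- rowSums(Tm); cs <- colSums(Tm)
    if (all(rs > 0)) {
      E <- outer(rs, cs) / sum(Tm)
      stat <- sum((Tm - E)^2 / E)
      df <- (nrow(Tm) - 1) * (ncol(Tm) - 1)
      p <- stats::pchisq(stat, df, lower.tail = FALSE)
    }
  }
  tibble::tibble(variable = variable, category = obs, n = unname(n_k),
                 prevalence = unname(prev_k),
                 statistic = stat, df = df, p_value = p)
}

#' Screen every candidate covariate
#'
#' Runs [screen_variable()] over a set of codebook variables and stacks the
#' results in the S1-table layout (variable, category, n, prevalence, p).
#'
#' @param ds A `coded_dataset`.
#' @param variables Variables to screen; defaults to the whole codebook.
#' @param outcome Stunting outcome definition.
#' @return A tibble, rows ordered by codebook order then category order.
#' @export
screen_all <- function(ds, variables = codebook_variables(ds),
                       outcome = c("total", "severe", "moderate")) {
  outcome <- match.arg(outcome)
  do.call(rbind, lapply(variables, function(v) screen_variable(ds, v, outcome)))
}

#' Build the polling candidate set from screening results
#'
#' Variables pass if their screening p-value is below `p_threshold`.
#' Screening informs but does not strictly gate inclusion: variables can be
#' forced in regardless of p-value (e.g. a family-planning indicator kept
#' for policy relevance) or forced out (e.g. the stratifier division, since
#' polling is run within strata). Output order is the input (codebook)
#' order, so the candidate set is deterministic.
#'
#' @param screens Output of [screen_all()].
#' @param p_threshold Significance gate (default 0.05).
#' @param force_include Variables to include regardless of p-value.
#' @param force_exclude Variables to drop regardless of p-value.
#' @return Character vector of candidate variable names.
#' @export
build_candidate_set <- function(screens, p_threshold = 0.05,
                                force_include = character(),
                                force_exclude = character()) {
  stopifnot(is.data.frame(screens),
            all(c("variable", "p_value") %in% names(screens)))
  vars <- unique(screens$variable)
  p <- vapply(vars, function(v) screens$p_value[screens$variable == v][1L],
              numeric(1))
  keep <- vars[!is.na(p) & p < p_threshold]
  keep <- union(keep, intersect(force_include, union(vars, force_include)))
  keep <- setdiff(keep, force_exclude)
  vars_all <- union(vars, force_include)
  vars_all[vars_all %in% keep]
}
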