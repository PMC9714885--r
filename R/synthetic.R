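#' Default covariate set for the synthetic generator
#'
#' Eleven coded covariates with illustrative marginals qualitatively
#' shaped like a mid-1990s Bangladesh children's-recode extract: a large
#' rural majority, mostly home deliveries, low parental schooling, a high
#' share of underweight mothers and few mothers under 145 cm. The values
#' are illustrative design choices for simulation — they are not estimates
#' from any survey.
#'
#' @return Named list: per variable, a list with `categories` and
#'   `marginal` (probabilities summing to 1, in category order).
#' @export
default_variables <- function() {
  list(
    child_sex = list(categories = c("male", "female"),
                     marginal = c(0.51, 0.49)),
    child_age_over_1y = list(categories = c("<=1y", ">1y"),
                             marginal = c(0.22, 0.78)),
    mother_education = list(categories = c("none", "primary", "secondary+"),
                            marginal = c(0.55, 0.27, 0.18)),
    father_education = list(categories = c("none", "primary", "secondary+"),
                            marginal = c(0.50, 0.27, 0.23)),
    mother_bmi = list(categories = c("underweight", "normal", "overweight+"),
                      marginal = c(0.38, 0.52, 0.10)),
    mother_height = list(categories = c("<145cm", ">=145cm"),
                         marginal = c(0.16, 0.84)),
    mother_age_at_birth = list(categories = c("<20", "20-34", ">=35"),
                               marginal = c(0.30, 0.60, 0.10)),
    delivery_place = list(categories = c("home", "facility"),
                          marginal = c(0.82, 0.18)),
    wealth_quintile = list(categories = c("poorest", "poorer", "middle",
                                          "richer", "richest"),
                           marginal = c(0.20, 0.20, 0.20, 0.20, 0.20)),
    residence = list(categories = c("urban", "rural"),
                     marginal = c(0.25, 0.75)),
    other_under5 = list(categories = c("none", "one", "two+"),
                        marginal = c(0.50, 0.38, 0.12))
  )
}

#' Default division layout for the synthetic generator
#'
#' Eight divisions with illustrative sampling shares and district counts
#' (64 districts in total), mirroring the administrative nesting of a
#' modern Bangladesh survey round.
#'
#' @return Named list: per division, a list with `share` and
#'   `n_districts`.
#' @export
default_divisions <- function() {
  list(
    Barisal    = list(share = 0.06, n_districts = 6L),
    Chittagong = list(share = 0.19, n_districts = 11L),
    Dhaka      = list(share = 0.26, n_districts = 13L),
    Khulna     = list(share = 0.10, n_districts = 10L),
    Mymensingh = list(share = 0.08, n_districts = 4L),
    Rajshahi   = list(share = 0.13, n_districts = 8L),
    Rangpur    = list(share = 0.11, n_districts = 8L),
    Sylhet     = list(share = 0.07, n_districts = 4L)
  )
}

#' Define a planted covariate profile
#'
#' A planted profile multiplies the baseline stunting odds by
#' `risk_multiplier` for every record matching all of its values, giving
#' the generated data a known ground truth for recovery tests.
#'
#' @param values Named character vector: variable name -> category value.
#' @param risk_multiplier Odds multiplier, finite and > 0 (1 = no effect).
#' @return An object of class `planted_profile`.
#' @export
planted_profile <- function(values, risk_multiplier) {
  stopifnot(is.character(values), !is.null(names(values)),
            all(nzchar(names(values))),
            is.numeric(risk_multiplier), length(risk_multiplier) == 1L,
            is.finite(risk_multiplier), risk_multiplier > 0)
  structure(list(values = values, risk_multiplier = risk_multiplier),
            class = "planted_profile")
}

#' Default planted profile
#'
#' The default planted risk profile places every value on the modal
#' category of its variable (rural residence, child over one year, home
#' delivery, mother without schooling, mother at least 145 cm). Under the
#' coverage ranking a winning profile is necessarily a high-mass one, so a
#' recoverable planted truth must dominate in mass as well as in risk;
#' planting on modal categories makes the planted cell the population-level
#' winner, which mirrors how the published winning profiles are themselves
#' conjunctions of prevalent categories.
#'
#' @param risk_multiplier Odds multiplier (default 3).
#' @return A [planted_profile()].
#' @export
default_planted_profile <- function(risk_multiplier = 3) {
  planted_profile(
    c(residence = "rural", child_age_over_1y = ">1y",
      delivery_place = "home", mother_education = "none",
      mother_height = ">=145cm"),
    risk_multiplier = risk_multiplier
  )
}

#' Specify a synthetic children's-recode-like dataset
#'
#' Full parameterization of the generator: covariate marginals, baseline
#' stunting probability, planted profile effects, the severe share of
#' stunting, the weight distribution, two-stage cluster/geography
#' structure, optional MCAR missingness, and the seed.
#'
#' @param n Number of child records.
#' @param variables Covariate definitions as in [default_variables()].
#' @param baseline_stunting_p Stunting probability for a record matching
#'   no planted profile (default 0.36).
#' @param planted List of [planted_profile()] objects (default: none).
#' @param severe_fraction Probability that a stunted child is severely
#'   stunted (default 1/3).
#' @param weight_distribution `"lognormal"` (mean-1 weights with
#'   `weight_sdlog` log-sd) or `"constant"` (all weights 1).
#' @param weight_sdlog Log-sd of the lognormal weights (default 0.5).
#' @param n_clusters Total number of primary sampling units (default 300),
#'   allocated to divisions proportionally to their shares.
#' @param divisions Division layout as in [default_divisions()].
#' @param dependence Pairwise covariate dependence in `[0, 1)`: each
#'   covariate draw uses a record-level shared uniform with this mixing
#'   probability, inducing positive association between covariates
#'   (default 0, independent draws).
#' @param missing_rate MCAR missingness rate applied to each covariate
#'   column (default 0).
#' @param seed Integer RNG seed; the generated dataset is a pure function
#'   of the spec.
#' @param survey_label Label stored on the dataset.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 5000L,
                           variables = default_variables(),
                           baseline_stunting_p = 0.36,
                           planted = list(),
                           severe_fraction = 1 / 3,
                           weight_distribution = c("lognormal", "constant"),
                           weight_sdlog = 0.5,
                           n_clusters = 300L,
                           divisions = default_divisions(),
                           dependence = 0,
                           missing_rate = 0,
                           seed = 1L,
                           survey_label = "synthetic") {
  weight_distribution <- match.arg(weight_distribution)
  stopifnot(n >= 1L, baseline_stunting_p > 0, baseline_stunting_p < 1,
            severe_fraction >= 0, severe_fraction <= 1,
            n_clusters >= 1L, dependence >= 0, dependence < 1,
            missing_rate >= 0, missing_rate < 1)
  if (inherits(planted, "planted_profile")) planted <- list(planted)
  for (v in names(variables)) {
    m <- variables[[v]]$marginal
    if (abs(sum(m) - 1) > 1e-8 || any(m < 0)) {
      stop("variable '", v, "': marginal probabilities must be nonnegative and sum to 1",
           call. = FALSE)
    }
    if (length(m) != length(variables[[v]]$categories)) {
      stop("variable '", v, "': marginal/category length mismatch", call. = FALSE)
    }
  }
  for (pp in planted) {
    stopifnot(inherits(pp, "planted_profile"))
    unknown <- setdiff(names(pp$values), names(variables))
    if (length(unknown) > 0L) {
      stop("planted profile uses unknown variable(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (v in names(pp$values)) {
      if (!pp$values[[v]] %in% variables[[v]]$categories) {
        stop("planted profile value '", pp$values[[v]],
             "' is not a category of '", v, "'", call. = FALSE)
      }
    }
  }
  shares <- vapply(divisions, function(d) d$share, numeric(1))
  if (abs(sum(shares) - 1) > 1e-8) {
    stop("division shares must sum to 1", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), variables = variables,
         baseline_stunting_p = baseline_stunting_p, planted = planted,
         severe_fraction = severe_fraction,
         weight_distribution = weight_distribution,
         weight_sdlog = weight_sdlog, n_clusters = as.integer(n_clusters),
         divisions = divisions, dependence = dependence,
         missing_rate = missing_rate, seed = as.integer(seed),
         survey_label = survey_label),
    class = "synthetic_spec"
  )
}

# Internal: draw categories from a marginal using supplied uniforms, so
# the same uniforms yield the same categories regardless of other
# parameters (common random numbers across specs differing only in
# planted effects).
.draw_categories <- function(u, categories, marginal) {
  br <- c(0, cumsum(marginal))
  br[length(br)] <- 1  # guard against cumsum rounding
  categories[findInterval(u, br, rightmost.closed = TRUE)]
}

#' Generate a synthetic children's-recode-like dataset
#'
#' Draws `n` child records according to the spec. Covariates come from
#' their marginals (optionally positively associated through the
#' `dependence` mixing parameter). The stunting indicator follows a
#' logistic model: baseline log-odds plus `log(risk_multiplier)` for every
#' planted profile the record matches in full. HAZ is then drawn
#' consistently with the indicator — severe (probability
#' `severe_fraction`) uniform on `[-5, -3)`, moderate uniform on
#' `[-3, -2)`, not stunted uniform on `[-2, 2]` — because the analysis
#' pipeline only ever thresholds HAZ, so matching the threshold semantics
#' is what the generator must guarantee. Division, district and cluster
#' labels realize a two-stage structure: clusters are nested in districts,
#' districts in divisions. The same spec (including seed) always yields
#' the identical dataset.
#'
#' @param spec A [synthetic_spec()].
#' @return A [coded_dataset()] with the covariates already coded and the
#'   codebook filled in.
#' @export
generate_children <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n

  # geography: division -> districts -> clusters, record inherits both
  div_names <- names(spec$divisions)
  shares <- vapply(spec$divisions, function(d) d$share, numeric(1))
  division <- div_names[.draw_categories(stats::runif(n), seq_along(div_names), shares)]
  clus_per_div <- pmax(1L, round(spec$n_clusters * shares / sum(shares)))
  cluster_id <- character(n)
  district <- character(n)
  for (i in seq_along(div_names)) {
    dn <- div_names[i]
    sel <- division == dn
    if (!any(sel)) next
    kc <- clus_per_div[i]
    cl <- sample.int(kc, sum(sel), replace = TRUE)
    cluster_id[sel] <- sprintf("%s_c%02d", dn, cl)
    # clusters assigned to the division's districts round-robin
    nd <- spec$divisions[[dn]]$n_districts
    district[sel] <- sprintf("%s_d%02d", dn, ((cl - 1L) %% nd) + 1L)
  }

  # covariates (fixed draw order: shared uniform, then one per variable)
  u_shared <- stats::runif(n)
  d <- list()
  for (v in names(spec$variables)) {
    u <- stats::runif(n)
    if (spec$dependence > 0) {
      pick <- stats::runif(n) < spec$dependence
      u[pick] <- u_shared[pick]
    }
    d[[v]] <- .draw_categories(u, spec$variables[[v]]$categories,
                               spec$variables[[v]]$marginal)
  }

  # stunting indicator: logistic in the planted profile matches
  eta <- rep(stats::qlogis(spec$baseline_stunting_p), n)
  for (pp in spec$planted) {
    match_all <- rep(TRUE, n)
    for (v in names(pp$values)) match_all <- match_all & d[[v]] == pp$values[[v]]
    eta <- eta + ifelse(match_all, log(pp$risk_multiplier), 0)
  }
  stunted <- stats::runif(n) < stats::plogis(eta)

  # HAZ consistent with the indicator
  severe <- stunted & (stats::runif(n) < spec$severe_fraction)
  u_haz <- stats::runif(n)
  haz <- ifelse(severe, -5 + 2 * u_haz,
         ifelse(stunted, -3 + u_haz, -2 + 4 * u_haz))

  weight <- if (spec$weight_distribution == "constant") {
    rep(1, n)
  } else {
    stats::rlnorm(n, meanlog = -spec$weight_sdlog^2 / 2, sdlog = spec$weight_sdlog)
  }

  if (spec$missing_rate > 0) {
    for (v in names(spec$variables)) {
      drop <- stats::runif(n) < spec$missing_rate
      d[[v]][drop] <- NA_character_
    }
  }

  data <- tibble::as_tibble(c(
    list(haz = haz, weight = weight, division = division,
         district = district, cluster_id = cluster_id),
    d))
  codebook <- lapply(names(spec$variables), function(v) {
    variable_spec(v, spec$variables[[v]]$categories, kind = "categorical")
  })
  coded_dataset(data, codebook = codebook, survey_label = spec$survey_label)
}

#' Machine-readable statement of the planted truth
#'
#' Recovery tests consume this manifest instead of reaching into the spec:
#' the planted profiles ordered by decreasing risk multiplier, the expected
#' qualitative winner (the strongest planted profile), and a flag for
#' null-structure datasets with nothing planted.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `null_structure`, `planted` (ordered), and
#'   `expected_winner` (`NULL` when nothing is planted).
#' @export
truth_manifest <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(spec$planted) == 0L) {
    return(list(null_structure = TRUE, planted = list(),
                expected_winner = NULL,
                baseline_stunting_p = spec$baseline_stunting_p,
                seed = spec$seed))
  }
  mult <- vapply(spec$planted, function(pp) pp$risk_multiplier, numeric(1))
  ord <- order(-mult)
  planted <- lapply(spec$planted[ord], function(pp) {
    list(values = as.list(pp$values), risk_multiplier = pp$risk_multiplier)
  })
  list(null_structure = FALSE, planted = planted,
       expected_winner = planted[[1L]],
       baseline_stunting_p = spec$baseline_stunting_p,
       seed = spec$seed)
}
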