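# Internal: per-profile cell table over a complete-case data frame.
#
# Profiles are encoded with a mixed-radix integer key built from the
# codebook category index of each subset variable, which keeps grouping,
# sorting and lexicographic tie-breaking exact and fast. Returns, per
# observed profile (any outcome): integer code matrix, label matrix, and
# masses/counts split by the binary outcome.
.cell_table <- function(d, subset, cats, gi) {
  w <- d$weight
  n <- nrow(d)
  codes <- matrix(0L, nrow = n, ncol = length(subset))
  for (j in seq_along(subset)) {
    codes[, j] <- match(d[[subset[j]]], cats[[j]])
  }
  key <- numeric(n)
  for (j in seq_along(subset)) {
    key <- key * length(cats[[j]]) + (codes[, j] - 1L)
  }
  agg <- rowsum(cbind(w * gi, w * (1 - gi), gi, 1 - gi), key, reorder = TRUE)
  keys <- as.numeric(rownames(agg))
  # decode keys back to per-variable category indices (1-based)
  k <- length(subset)
  pcodes <- matrix(0L, nrow = length(keys), ncol = k)
  rem <- keys
  for (j in rev(seq_len(k))) {
    Kj <- length(cats[[j]])
    pcodes[, j] <- as.integer(rem %% Kj) + 1L
    rem <- (rem - (rem %% Kj)) / Kj
  }
  labels <- matrix("", nrow = length(keys), ncol = k)
  for (j in seq_len(k)) labels[, j] <- cats[[j]][pcodes[, j]]
  colnames(labels) <- subset
  list(codes = pcodes, labels = labels,
       m1 = unname(agg[, 1]), m0 = unname(agg[, 2]),
       n1 = as.integer(agg[, 3]), n0 = as.integer(agg[, 4]),
       n_records = n)
}

.insufficient_support <- function(msg) {
  stop(structure(
    class = c("profilepoll_insufficient_support", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Internal: rank profiles and extract winner/runner-up. `ct` is a cell
# table from .cell_table(); the outcome group is g = 1 (swap m1/m0 and
# n1/n0 upstream to poll g = 0). Shared by poll() and run_search().
.poll_core <- function(ct, convention, min_cell) {
  m_g_total <- sum(ct$m1)          # total mass of the outcome group
  qualify <- which(ct$m1 > 0 & ct$n1 >= min_cell)
  if (length(qualify) < 2L) {
    .insufficient_support(sprintf(
      "fewer than two profiles with outcome mass and support >= %d (found %d)",
      min_cell, length(qualify)))
  }
  crit <- switch(convention,
    "coverage-rank" = ct$m1[qualify],
    "conditional-rank" = ct$m1[qualify] / (ct$m1[qualify] + ct$m0[qualify])
  )
  # order: criterion descending, ties broken lexicographically on the
  # coded (integer) category values of the profile
  ord_args <- c(list(-crit),
                lapply(seq_len(ncol(ct$codes)),
                       function(j) ct$codes[qualify, j]))
  ord <- do.call(order, ord_args)
  wi <- qualify[ord[1L]]
  ri <- qualify[ord[2L]]
  crit_w <- crit[ord[1L]]
  crit_r <- crit[ord[2L]]
  list(
    winner = stats::setNames(ct$labels[wi, ], colnames(ct$labels)),
    runner_up = stats::setNames(ct$labels[ri, ], colnames(ct$labels)),
    coverage = ct$m1[wi] / m_g_total,
    edge = crit_w / crit_r,
    tie = crit_w == crit_r,
    criterion_winner = crit_w,
    criterion_runner_up = crit_r,
    n_profiles = nrow(ct$codes),
    n_qualifying = length(qualify),
    n_effective = ct$n_records
  )
}

#' Weighted joint distribution over (outcome, profile)
#'
#' Builds the empirical joint mass of the binary stunting outcome and the
#' covariate profile over a variable subset: the mass of cell `(g, c)` is
#' the sum of sampling weights of complete-case records whose profile
#' equals `c` and whose outcome equals `g`. Cells with zero mass are
#' absent. This is the object every polling statistic is a ratio of.
#'
#' @param ds A `coded_dataset` with codings applied.
#' @param subset Non-empty character vector of codebook variable names.
#' @param outcome Stunting outcome definition: `"total"` (HAZ < -2) or
#'   `"severe"` (HAZ < -3); `"moderate"` is accepted for completeness.
#' @return An object of class `joint_mass`: a list with `cells` (a tibble
#'   with one row per non-empty cell: the subset columns, `g`, `mass`,
#'   `n`), `subset`, `outcome`, `categories` (per-variable category
#'   orders), `total_mass` and `n_records`.
#' @export
joint_distribution <- function(ds, subset, outcome = c("total", "severe", "moderate")) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(ds, "coded_dataset"))
  if (length(subset) == 0L) stop("subset must be non-empty", call. = FALSE)
  cats <- lapply(subset, function(v) variable_categories(ds, v))
  cc <- complete_cases(ds, subset, quiet = TRUE)
  d <- cc$data
  gi <- .stunting_indicator(d$haz, outcome)
  ct <- .cell_table(d, subset, cats, gi)

  rows_g1 <- ct$m1 > 0
  rows_g0 <- ct$m0 > 0
  cells <- tibble::as_tibble(as.data.frame(
    rbind(ct$labels[rows_g1, , drop = FALSE], ct$labels[rows_g0, , drop = FALSE]),
    stringsAsFactors = FALSE))
  cells$g <- c(rep(1L, sum(rows_g1)), rep(0L, sum(rows_g0)))
  cells$mass <- c(ct$m1[rows_g1], ct$m0[rows_g0])
  cells$n <- c(ct$n1[rows_g1], ct$n0[rows_g0])

  structure(
    list(cells = cells, subset = subset, outcome = outcome,
         categories = stats::setNames(cats, subset),
         total_mass = sum(d$weight), n_records = nrow(d)),
    class = "joint_mass"
  )
}

#' @export
print.joint_mass <- function(x, ...) {
  cat("<joint_mass> outcome:", x$outcome,
      "| subset:", paste(x$subset, collapse = " + "), "\n")
  cat("  ", nrow(x$cells), " non-empty cell(s) over ", x$n_records,
      " record(s), total mass ", format(x$total_mass), "\n", sep = "")
  invisible(x)
}

# Internal: rebuild a cell table (as from .cell_table) from a joint_mass.
.ct_from_joint <- function(jm) {
  k <- length(jm$subset)
  lab <- as.matrix(jm$cells[, jm$subset, drop = FALSE])
  key <- apply(lab, 1L, paste, collapse = "\x1f")
  ukey <- unique(key)
  idx <- match(key, ukey)
  m1 <- m0 <- numeric(length(ukey))
  n1 <- n0 <- integer(length(ukey))
  g1 <- jm$cells$g == 1L
  m1[idx[g1]] <- jm$cells$mass[g1]
  n1[idx[g1]] <- jm$cells$n[g1]
  m0[idx[!g1]] <- jm$cells$mass[!g1]
  n0[idx[!g1]] <- jm$cells$n[!g1]
  labels <- lab[match(ukey, key), , drop = FALSE]
  colnames(labels) <- jm$subset
  codes <- matrix(0L, nrow = length(ukey), ncol = k)
  for (j in seq_len(k)) codes[, j] <- match(labels[, j], jm$categories[[j]])
  list(codes = codes, labels = labels, m1 = m1, m0 = m0, n1 = n1, n0 = n0,
       n_records = jm$n_records)
}

#' Conditional outcome frequency given a profile
#'
#' `P(g | c) = m_gc / sum_g m_gc`: the mass of cell `(g, c)` divided by the
#' total mass of profile `c` across both outcome values. Returns 0 when the
#' profile is observed but only with the other outcome; asks for an
#' unobserved profile is an error.
#'
#' @param jm A `joint_mass` from [joint_distribution()].
#' @param g Outcome value, 0 or 1.
#' @param profile Character vector of category values, one per subset
#'   variable, in subset order (names, if present, are checked).
#' @return A probability in `[0, 1]`.
#' @export
conditional_frequency <- function(jm, g, profile) {
  stopifnot(inherits(jm, "joint_mass"), g %in% c(0L, 1L))
  profile <- as.character(profile)
  if (length(profile) != length(jm$subset)) {
    stop("profile must have one value per subset variable", call. = FALSE)
  }
  if (!is.null(names(profile)) && !identical(names(profile), jm$subset)) {
    profile <- profile[jm$subset]
  }
  sel <- rep(TRUE, nrow(jm$cells))
  for (j in seq_along(jm$subset)) {
    sel <- sel & jm$cells[[jm$subset[j]]] == profile[j]
  }
  if (!any(sel)) stop("profile not observed in the joint distribution", call. = FALSE)
  denom <- sum(jm$cells$mass[sel])
  num <- sum(jm$cells$mass[sel & jm$cells$g == g])
  num / denom
}

#' Poll a joint distribution: winner, runner-up, coverage and edge
#'
#' Identifies the winning profile for outcome group `g` and quantifies it
#' with two statistics: *coverage*, the winning cell's mass divided by the
#' total mass of the outcome group (the share of, say, stunted children the
#' profile accounts for), and *edge*, the ratio of the winner's ranking
#' criterion to the runner-up's (confidence that the winner is really
#' first).
#'
#' Two ranking conventions are supported. `"coverage-rank"` (default)
#' ranks profiles by their mass within the outcome group, `m_gc` —
#' equivalently by coverage — so the winner is the profile accounting for
#' the largest share of the outcome group, and the edge is the ratio of the
#' top two coverages. `"conditional-rank"` ranks by the conditional
#' frequency `P(g | c)`, so the winner is the profile whose members are
#' most likely to have the outcome, and the edge is the ratio of the top
#' two conditional frequencies. Ties are broken lexicographically on the
#' coded category values and flagged in the result.
#'
#' Only profiles with at least `min_cell` unweighted records in the
#' outcome-`g` cell qualify as winner or runner-up; without a support floor
#' a single-record profile with `P(g|c) = 1` would trivially win under the
#' conditional ranking. The coverage denominator always includes every
#' observed profile.
#'
#' @param jm A `joint_mass` from [joint_distribution()].
#' @param g Outcome value to poll (default 1 = has the outcome).
#' @param convention `"coverage-rank"` or `"conditional-rank"`.
#' @param min_cell Minimum unweighted support of the `(g, c)` cell for a
#'   profile to qualify (default 25).
#' @return An object of class `polling_result`: subset, outcome,
#'   convention, `winner` and `runner_up` (named character vectors),
#'   `coverage`, `edge` (>= 1), `tie` flag, qualifying/observed profile
#'   counts and the effective sample size.
#' @export
poll <- function(jm, g = 1L, convention = c("coverage-rank", "conditional-rank"),
                 min_cell = 25L) {
  convention <- match.arg(convention)
  stopifnot(inherits(jm, "joint_mass"), g %in% c(0L, 1L))
  ct <- .ct_from_joint(jm)
  if (g == 0L) {
    ct <- list(codes = ct$codes, labels = ct$labels,
               m1 = ct$m0, m0 = ct$m1, n1 = ct$n0, n0 = ct$n1,
               n_records = ct$n_records)
  }
  res <- .poll_core(ct, convention, min_cell)
  structure(
    c(list(subset = jm$subset, outcome = jm$outcome, g = as.integer(g),
           convention = convention, min_cell = as.integer(min_cell)),
      res),
    class = "polling_result"
  )
}

#' @export
print.polling_result <- function(x, ...) {
  cat("<polling_result> outcome:", x$outcome, "| convention:", x$convention, "\n")
  cat("  winner:    ", paste(names(x$winner), x$winner, sep = "=", collapse = ", "), "\n")
  cat("  runner-up: ", paste(names(x$runner_up), x$runner_up, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  coverage %.3f | edge %.2f%s | n=%d (%d/%d profiles qualify)\n",
              x$coverage, x$edge, if (isTRUE(x$tie)) " (tie)" else "",
              x$n_effective, x$n_qualifying, x$n_profiles))
  invisible(x)
}
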