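#' Enumerate all k-variable subsets of the candidate set
#'
#' All `choose(n, k)` unordered subsets, in lexicographic order of the
#' candidate indices (so the order is deterministic given the candidate
#' order). Profiles are order-free conjunctions, so unordered subsets are
#' the right unit of enumeration: eleven candidates at k = 5 give the 462
#' polling analyses of a full search.
#'
#' @param candidates Character vector of candidate variable names.
#' @param k Subset size.
#' @return A list of character vectors, each of length `k`.
#' @export
#' @examples
#' length(enumerate_subsets(paste0("v", 1:11), 5))  # 462
enumerate_subsets <- function(candidates, k) {
  n <- length(candidates)
  if (k > n) stop("k (", k, ") exceeds the number of candidates (", n, ")",
                  call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  idx <- utils::combn(n, k)
  lapply(seq_len(ncol(idx)), function(j) candidates[idx[, j]])
}

#' Configure a profile search
#'
#' @param candidates Candidate variable names (screened and coded).
#' @param k Subset size (default 5, the size at which profile specificity
#'   and coverage balance best in this family of analyses).
#' @param outcome Stunting outcome definition.
#' @param convention Polling ranking convention, see [poll()].
#' @param ranking How competing subsets are ordered within a stratum:
#'   `"coverage-then-edge"` (default; coverage descending, edge breaks
#'   ties, then lexicographic subset order), `"edge-then-coverage"`, or
#'   `"product"` (by `coverage * log(edge)`).
#' @param min_cell Minimum unweighted winning-cell support, see [poll()].
#' @param stratify Column defining the strata (default `"division"`), or
#'   `NULL` for a national-only search.
#' @param include_national Also run the pooled (no stratum filter) search
#'   under the stratum label `"national"`.
#' @return A list of class `search_config`.
#' @export
search_config <- function(candidates, k = 5L,
                          outcome = c("total", "severe", "moderate"),
                          convention = c("coverage-rank", "conditional-rank"),
                          ranking = c("coverage-then-edge", "edge-then-coverage", "product"),
                          min_cell = 25L, stratify = "division",
                          include_national = TRUE) {
  outcome <- match.arg(outcome)
  convention <- match.arg(convention)
  ranking <- match.arg(ranking)
  stopifnot(length(candidates) >= 1L, k >= 1L, k <= length(candidates))
  structure(
    list(candidates = as.character(candidates), k = as.integer(k),
         outcome = outcome, convention = convention, ranking = ranking,
         min_cell = as.integer(min_cell), stratify = stratify,
         include_national = isTRUE(include_national)),
    class = "search_config"
  )
}

# Internal: order rows of a per-stratum result table under a ranking rule.
.rank_order <- function(tab, ranking) {
  switch(ranking,
    "coverage-then-edge" = order(-tab$coverage, -tab$edge, tab$subset_id),
    "edge-then-coverage" = order(-tab$edge, -tab$coverage, tab$subset_id),
    "product" = order(-(tab$coverage * log(tab$edge)), tab$subset_id)
  )
}

#' Exhaustive polling search over covariate subsets
#'
#' For each stratum (each observed level of `cfg$stratify`, plus the pooled
#' `"national"` stratum), polls every k-variable subset of the candidate
#' set on that stratum's complete cases — each subset analysis uses its own
#' maximal complete-case sample — and ranks the subsets by the configured
#' rule. The top-ranked entry is that stratum's winning subset/profile.
#' Subsets with insufficient support (fewer than two qualifying profiles)
#' are excluded from the ranking and counted.
#'
#' @param ds A `coded_dataset` with codings applied.
#' @param cfg A [search_config()].
#' @return An object of class `search_result`: `config`, `survey_label`,
#'   `n_analyses` (`choose(n, k)`), and `strata`, a named list with, per
#'   stratum, the ranked results tibble (`rank`, `subset_id`, `subset`,
#'   winner profile columns, `coverage`, `edge`, `tie`, `n_effective`), the
#'   `chosen` entry (structured winner), and `n_insufficient`.
#' @export
run_search <- function(ds, cfg) {
  stopifnot(inherits(ds, "coded_dataset"), inherits(cfg, "search_config"))
  missing_vars <- setdiff(cfg$candidates, codebook_variables(ds))
  if (length(missing_vars) > 0L) {
    stop("candidates not in codebook: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  subsets <- enumerate_subsets(cfg$candidates, cfg$k)
  cats_all <- stats::setNames(
    lapply(cfg$candidates, function(v) variable_categories(ds, v)),
    cfg$candidates)

  d_all <- ds$data
  g_all <- .stunting_indicator(d_all$haz, cfg$outcome)

  strata <- list(national = rep(TRUE, nrow(d_all)))
  if (!is.null(cfg$stratify)) {
    if (!cfg$stratify %in% names(d_all)) {
      stop("stratifier '", cfg$stratify, "' not found", call. = FALSE)
    }
    lv <- sort(unique(as.character(d_all[[cfg$stratify]])))
    for (s in lv) strata[[s]] <- !is.na(d_all[[cfg$stratify]]) &
                                  as.character(d_all[[cfg$stratify]]) == s
  }
  if (!cfg$include_national) strata$national <- NULL

  out_strata <- list()
  for (s in names(strata)) {
    d_s <- d_all[strata[[s]], , drop = FALSE]
    g_s <- g_all[strata[[s]]]
    rows <- vector("list", length(subsets))
    chosen_details <- vector("list", length(subsets))
    n_insufficient <- 0L
    for (i in seq_along(subsets)) {
      sub <- subsets[[i]]
      ok <- !is.na(g_s)
      for (v in sub) ok <- ok & !is.na(d_s[[v]])
      if (!any(ok)) { n_insufficient <- n_insufficient + 1L; next }
      ct <- .cell_table(d_s[ok, , drop = FALSE], sub, cats_all[sub], g_s[ok])
      res <- tryCatch(.poll_core(ct, cfg$convention, cfg$min_cell),
                      profilepoll_insufficient_support = function(e) NULL)
      if (is.null(res)) { n_insufficient <- n_insufficient + 1L; next }
      rows[[i]] <- tibble::tibble(
        subset_id = i,
        subset = paste(sub, collapse = "+"),
        winner = paste(names(res$winner), res$winner, sep = "=", collapse = "|"),
        coverage = res$coverage, edge = res$edge, tie = res$tie,
        n_effective = res$n_effective
      )
      chosen_details[[i]] <- c(list(subset = sub), res)
    }
    keep <- !vapply(rows, is.null, logical(1))
    if (!any(keep)) {
      out_strata[[s]] <- list(table = NULL, chosen = NULL,
                              n_insufficient = n_insufficient)
      warning("stratum '", s, "': every subset had insufficient support",
              call. = FALSE)
      next
    }
    tab <- do.call(rbind, rows[keep])
    ord <- .rank_order(tab, cfg$ranking)
    tab <- tab[ord, , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    tab <- tab[, c("rank", "subset_id", "subset", "winner",
                   "coverage", "edge", "tie", "n_effective")]
    out_strata[[s]] <- list(
      table = tab,
      chosen = chosen_details[[tab$subset_id[1L]]],
      n_insufficient = n_insufficient
    )
  }

  structure(
    list(config = cfg, survey_label = ds$survey_label,
         n_analyses = choose(length(cfg$candidates), cfg$k),
         strata = out_strata),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result>", if (!is.na(x$survey_label)) paste0("[", x$survey_label, "]"),
      "\n  ", x$n_analyses, " subset analyses per stratum (k=", x$config$k,
      ", ", length(x$config$candidates), " candidates, ",
      x$config$convention, ", ranking ", x$config$ranking, ")\n", sep = "")
  for (s in names(x$strata)) {
    ch <- x$strata[[s]]$chosen
    if (is.null(ch)) {
      cat(sprintf("  %-12s  (no qualifying subset)\n", s)); next
    }
    cat(sprintf("  %-12s  %s  coverage %.2f  edge %.2f\n", s,
                paste(names(ch$winner), ch$winner, sep = "=", collapse = ", "),
                ch$coverage, ch$edge))
  }
  invisible(x)
}

#' Extract the winners table from a search result
#'
#' One row per stratum in the reporting layout used for the survey tables:
#' stratum, the winning profile as `variable=value` fields, coverage and
#' edge.
#'
#' @param res A `search_result`.
#' @return A tibble with columns `stratum`, `value1` ... `valuek`
#'   (each `variable=value`), `coverage`, `edge`.
#' @export
winners_table <- function(res) {
  stopifnot(inherits(res, "search_result"))
  k <- res$config$k
  rows <- lapply(names(res$strata), function(s) {
    ch <- res$strata[[s]]$chosen
    if (is.null(ch)) return(NULL)
    vals <- paste(names(ch$winner), ch$winner, sep = "=")
    row <- c(list(stratum = s),
             stats::setNames(as.list(vals), paste0("value", seq_len(k))),
             list(coverage = ch$coverage, edge = ch$edge))
    tibble::as_tibble(row)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Write a search result to disk
#'
#' Emits, under `dir`: `winners.csv` (per-stratum winning profile with
#' coverage and edge rounded to 2 decimals, the layout of the published
#' polling tables), one `ranked_<stratum>.csv` per stratum with the full
#' ranked subset list at full precision, and `manifest.json` recording the
#' configuration, the analysis counts and the chosen entries at full
#' precision. Output is deterministic: identical inputs produce
#' byte-identical files.
#'
#' @param res A `search_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_search_result <- function(res, dir) {
  stopifnot(inherits(res, "search_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  wt <- winners_table(res)
  if (!is.null(wt)) {
    wt$coverage <- sprintf("%.2f", wt$coverage)
    wt$edge <- sprintf("%.2f", wt$edge)
    utils::write.table(as.data.frame(wt), file.path(dir, "winners.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
  }
  for (s in names(res$strata)) {
    tab <- res$strata[[s]]$table
    if (is.null(tab)) next
    out <- as.data.frame(tab)
    out$coverage <- sprintf("%.17g", out$coverage)
    out$edge <- sprintf("%.17g", out$edge)
    utils::write.table(out, file.path(dir, paste0("ranked_", s, ".csv")),
                       sep = ",", row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    package = "profilepoll",
    survey_label = res$survey_label,
    config = unclass(res$config),
    n_analyses = res$n_analyses,
    strata = lapply(res$strata, function(st) {
      if (is.null(st$chosen)) {
        return(list(n_insufficient = st$n_insufficient))
      }
      list(
        subset = st$chosen$subset,
        winner = as.list(st$chosen$winner),
        runner_up = as.list(st$chosen$runner_up),
        coverage = st$chosen$coverage,
        edge = st$chosen$edge,
        tie = st$chosen$tie,
        n_effective = st$chosen$n_effective,
        n_insufficient = st$n_insufficient
      )
    })
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
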