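#' Compare winning profiles across survey rounds
#'
#' For each pair of consecutive results (e.g. two survey years) and each
#' stratum, reports which variables entered or left the winning profile,
#' the coverage and edge changes, and whether profile diversity increased
#' (coverage of the winner fell — a lower share of the outcome group is
#' accounted for by any single profile, so the profiles are more diverse).
#' Strata present in only one round (e.g. a division created between
#' surveys) are reported as not comparable.
#'
#' @param results A named list of two or more `search_result` objects, in
#'   chronological order; names label the rounds.
#' @return A tibble with one row per (round pair, stratum): `from`, `to`,
#'   `stratum`, `comparable`, `vars_entered`, `vars_left` (comma-separated,
#'   empty when unchanged), `coverage_from`, `coverage_to`,
#'   `coverage_delta`, `edge_from`, `edge_to`, `edge_delta`,
#'   `diversity_increased`.
#' @export
compare_surveys <- function(results) {
  stopifnot(is.list(results), length(results) >= 2L)
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    names(results) <- paste0("round", seq_along(results))
  }
  for (r in results) stopifnot(inherits(r, "search_result"))

  out <- list()
  for (i in seq_len(length(results) - 1L)) {
    a <- results[[i]]; b <- results[[i + 1L]]
    la <- names(results)[i]; lb <- names(results)[i + 1L]
    strata <- union(names(a$strata), names(b$strata))
    for (s in strata) {
      cha <- if (s %in% names(a$strata)) a$strata[[s]]$chosen else NULL
      chb <- if (s %in% names(b$strata)) b$strata[[s]]$chosen else NULL
      if (is.null(cha) || is.null(chb)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          from = la, to = lb, stratum = s, comparable = FALSE,
          vars_entered = NA_character_, vars_left = NA_character_,
          coverage_from = NA_real_, coverage_to = NA_real_,
          coverage_delta = NA_real_, edge_from = NA_real_,
          edge_to = NA_real_, edge_delta = NA_real_,
          diversity_increased = NA)
        next
      }
      entered <- setdiff(chb$subset, cha$subset)
      left <- setdiff(cha$subset, chb$subset)
      out[[length(out) + 1L]] <- tibble::tibble(
        from = la, to = lb, stratum = s, comparable = TRUE,
        vars_entered = paste(entered, collapse = ","),
        vars_left = paste(left, collapse = ","),
        coverage_from = cha$coverage, coverage_to = chb$coverage,
        coverage_delta = chb$coverage - cha$coverage,
        edge_from = cha$edge, edge_to = chb$edge,
        edge_delta = chb$edge - cha$edge,
        diversity_increased = chb$coverage < cha$coverage)
    }
  }
  do.call(rbind, out)
}
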