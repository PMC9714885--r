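# Independent brute-force oracles. These deliberately share no code with
# the package internals: dictionary accumulation by explicit row loops,
# winner selection by explicit scans.

# stunting indicator straight from the thresholds
oracle_indicator <- function(haz, outcome = "total") {
  if (outcome == "total") as.integer(haz < -2)
  else if (outcome == "severe") as.integer(haz < -3)
  else as.integer(haz >= -3 & haz < -2)
}

# joint masses by looping over records into a named-list dictionary;
# returns a data.frame: one row per profile with m1, m0, n1, n0 and the
# profile values.
oracle_cells <- function(ds, subset, outcome = "total") {
  d <- ds$data
  keep <- !is.na(d$haz)
  for (v in subset) keep <- keep & !is.na(d[[v]])
  d <- d[keep, , drop = FALSE]
  gi <- oracle_indicator(d$haz, outcome)
  dict <- list()
  for (i in seq_len(nrow(d))) {
    vals <- vapply(subset, function(v) d[[v]][i], character(1))
    key <- paste(vals, collapse = "\x1f")
    if (is.null(dict[[key]])) {
      dict[[key]] <- list(vals = vals, m1 = 0, m0 = 0, n1 = 0L, n0 = 0L)
    }
    e <- dict[[key]]
    if (gi[i] == 1L) { e$m1 <- e$m1 + d$weight[i]; e$n1 <- e$n1 + 1L }
    else { e$m0 <- e$m0 + d$weight[i]; e$n0 <- e$n0 + 1L }
    dict[[key]] <- e
  }
  out <- do.call(rbind, lapply(dict, function(e) {
    df <- as.data.frame(as.list(e$vals), stringsAsFactors = FALSE)
    names(df) <- subset
    df$m1 <- e$m1; df$m0 <- e$m0; df$n1 <- e$n1; df$n0 <- e$n0
    df
  }))
  rownames(out) <- NULL
  list(cells = out, n_records = nrow(d))
}

# full polling oracle: winner/runner-up by explicit max scans with
# lexicographic tie-break on coded category indices
oracle_poll <- function(ds, subset, outcome = "total",
                        convention = "coverage-rank", min_cell = 1L) {
  oc <- oracle_cells(ds, subset, outcome)
  cells <- oc$cells
  cats <- lapply(subset, function(v) variable_categories(ds, v))
  codes <- matrix(0L, nrow = nrow(cells), ncol = length(subset))
  for (j in seq_along(subset)) codes[, j] <- match(cells[[subset[j]]], cats[[j]])

  m_g <- sum(cells$m1)
  qual <- which(cells$m1 > 0 & cells$n1 >= min_cell)
  if (length(qual) < 2L) return(NULL)
  crit <- if (convention == "coverage-rank") cells$m1 else cells$m1 / (cells$m1 + cells$m0)

  beats <- function(a, b) {  # does profile-index a rank before b?
    if (crit[a] != crit[b]) return(crit[a] > crit[b])
    for (j in seq_along(subset)) {
      if (codes[a, j] != codes[b, j]) return(codes[a, j] < codes[b, j])
    }
    FALSE
  }
  win <- qual[1L]
  for (a in qual[-1L]) if (beats(a, win)) win <- a
  rest <- setdiff(qual, win)
  run <- rest[1L]
  for (a in rest[-1L]) if (beats(a, run)) run <- a

  list(
    winner = setNames(vapply(subset, function(v) cells[[v]][win], character(1)), subset),
    runner_up = setNames(vapply(subset, function(v) cells[[v]][run], character(1)), subset),
    coverage = cells$m1[win] / m_g,
    edge = crit[win] / crit[run],
    tie = crit[win] == crit[run],
    n_effective = oc$n_records
  )
}

# textbook Pearson chi-square from an unweighted contingency table built
# by counting loops
oracle_pearson <- function(x, y) {
  xs <- sort(unique(x)); ys <- sort(unique(y))
  O <- matrix(0, nrow = length(xs), ncol = length(ys))
  for (i in seq_along(x)) {
    O[match(x[i], xs), match(y[i], ys)] <- O[match(x[i], xs), match(y[i], ys)] + 1
  }
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  list(statistic = sum((O - E)^2 / E),
       df = (length(xs) - 1) * (length(ys) - 1))
}
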