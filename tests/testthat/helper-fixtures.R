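# Fixture builders, all programmatic.

# minimal valid coded dataset from parallel vectors; covariates passed as
# named lists of category vectors get codebook entries with categories in
# first-appearance-sorted order unless `cats` overrides them
make_ds <- function(haz, weight = rep(1, length(haz)),
                    division = rep("Dhaka", length(haz)),
                    district = rep("Dhaka_d01", length(haz)),
                    covariates = list(), cats = list(),
                    survey_label = "fixture") {
  data <- tibble::tibble(haz = haz, weight = weight,
                         division = division, district = district)
  for (v in names(covariates)) data[[v]] <- covariates[[v]]
  codebook <- lapply(names(covariates), function(v) {
    cc <- if (!is.null(cats[[v]])) cats[[v]] else sort(unique(stats::na.omit(covariates[[v]])))
    variable_spec(v, cc)
  })
  coded_dataset(data, codebook = codebook, survey_label = survey_label)
}

# one Dirichlet(1,...,1) draw without extra dependencies
rdirichlet1 <- function(k) {
  g <- stats::rgamma(k, 1)
  g / sum(g)
}

# randomized polling test dataset: 3-6 variables, 2-3 categories each,
# n <= 1000, continuous or unit weights, stunting tied loosely to one
# variable so cells are non-degenerate
random_ds <- function(seed) {
  set.seed(seed)
  n <- sample(50:1000, 1)
  p <- sample(3:6, 1)
  covs <- list()
  cats <- list()
  for (j in seq_len(p)) {
    k <- sample(2:3, 1)
    labs <- paste0("v", j, letters[1:k])
    covs[[paste0("v", j)]] <- sample(labs, n, replace = TRUE, prob = rdirichlet1(k))
    cats[[paste0("v", j)]] <- labs
  }
  pr <- 0.2 + 0.4 * (covs$v1 == cats$v1[1])
  stunted <- stats::runif(n) < pr
  haz <- ifelse(stunted, stats::runif(n, -4.5, -2.01), stats::runif(n, -1.99, 1.5))
  w <- if (stats::runif(1) < 0.5) rep(1, n) else stats::rlnorm(n, 0, 0.4)
  make_ds(haz, weight = w, covariates = covs, cats = cats)
}
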