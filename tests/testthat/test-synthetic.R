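test_that("generation is a pure function of the spec", {
  spec <- synthetic_spec(n = 800, planted = list(default_planted_profile(2)),
                         missing_rate = 0.03, seed = 99)
  ds1 <- generate_children(spec)
  ds2 <- generate_children(spec)
  expect_identical(ds1, ds2)
})

test_that("a unit risk multiplier reproduces the no-planting dataset at the same seed", {
  base <- synthetic_spec(n = 1000, seed = 12)
  null_mult <- synthetic_spec(n = 1000, seed = 12,
                              planted = list(default_planted_profile(1)))
  expect_identical(generate_children(base)$data, generate_children(null_mult)$data)
})

test_that("observed prevalence tracks the baseline within sampling error", {
  spec <- synthetic_spec(n = 1000, baseline_stunting_p = 0.36, seed = 21)
  ds <- generate_children(spec)
  pt <- weighted_prevalence(ds, "total")
  expect_lt(abs(pt$prevalence - 0.36), 0.04)
})

test_that("category frequencies recover the spec marginals at 3-sigma", {
  spec <- synthetic_spec(n = 4000, seed = 33)
  ds <- generate_children(spec)
  n <- n_records(ds)
  for (v in names(spec$variables)) {
    cats <- spec$variables[[v]]$categories
    marg <- spec$variables[[v]]$marginal
    for (j in seq_along(cats)) {
      obs <- mean(ds$data[[v]] == cats[j])
      tol <- 3 * sqrt(marg[j] * (1 - marg[j]) / n)
      expect_lt(abs(obs - marg[j]), max(tol, 1e-9))
    }
  }
})

test_that("every generated HAZ is consistent with its severity class", {
  spec <- synthetic_spec(n = 2000, severe_fraction = 0.4, seed = 44,
                         planted = list(default_planted_profile(3)))
  ds <- generate_children(spec)
  cls <- classify_stunting(ds$data$haz)
  expect_true(all(cls %in% c("not_stunted", "moderate", "severe")))
  expect_true(all(ds$data$haz >= -5 & ds$data$haz <= 2))
  # severe share among the stunted near the spec value
  sev_share <- mean(cls[cls != "not_stunted"] == "severe")
  expect_lt(abs(sev_share - 0.4), 0.05)
})

test_that("planted-profile coverage among the stunted is monotone in the multiplier", {
  planted_vars <- names(default_planted_profile(1)$values)
  for (seed in c(1, 2, 3)) {
    cov_seq <- vapply(c(1, 2, 4, 8), function(m) {
      spec <- synthetic_spec(n = 10000, seed = seed,
                             planted = list(default_planted_profile(m)))
      ds <- generate_children(spec)
      d <- ds$data
      stunted <- d$haz < -2
      match_all <- rep(TRUE, nrow(d))
      pp <- default_planted_profile(m)$values
      for (v in names(pp)) match_all <- match_all & d[[v]] == pp[[v]]
      sum(d$weight[stunted & match_all]) / sum(d$weight[stunted])
    }, numeric(1))
    expect_true(all(diff(cov_seq) >= 0))
  }
})

test_that("geography is nested: clusters within districts within divisions", {
  ds <- generate_children(synthetic_spec(n = 3000, seed = 8))
  d <- ds$data
  # each cluster maps to exactly one district and one division
  expect_true(all(tapply(d$district, d$cluster_id,
                         function(x) length(unique(x))) == 1L))
  expect_true(all(startsWith(d$cluster_id, d$division)))
  expect_true(all(startsWith(d$district, d$division)))
})

test_that("weights are positive with the requested distribution", {
  const <- generate_children(synthetic_spec(n = 500, seed = 2,
                                            weight_distribution = "constant"))
  expect_true(all(const$data$weight == 1))
  logn <- generate_children(synthetic_spec(n = 5000, seed = 2,
                                           weight_distribution = "lognormal",
                                           weight_sdlog = 0.5))
  expect_true(all(logn$data$weight > 0))
  expect_lt(abs(mean(logn$data$weight) - 1), 0.05)
})

test_that("MCAR missingness lands near its configured rate per covariate", {
  spec <- synthetic_spec(n = 5000, missing_rate = 0.1, seed = 3)
  ds <- generate_children(spec)
  rates <- vapply(names(spec$variables),
                  function(v) mean(is.na(ds$data[[v]])), numeric(1))
  expect_true(all(abs(rates - 0.1) < 0.02))
  # haz and weight are never blanked
  expect_false(anyNA(ds$data$haz))
  expect_false(anyNA(ds$data$weight))
})

test_that("infeasible specs fail loudly", {
  expect_error(synthetic_spec(planted = list(planted_profile(c(nope = "x"), 2))),
               "unknown variable")
  expect_error(synthetic_spec(planted = list(
    planted_profile(c(residence = "suburban"), 2))), "not a category")
  bad_marg <- default_variables()
  bad_marg$residence$marginal <- c(0.7, 0.7)
  expect_error(synthetic_spec(variables = bad_marg), "sum to 1")
})

test_that("the truth manifest states the planted structure", {
  weak <- planted_profile(c(residence = "urban"), 1.5)
  strong <- default_planted_profile(4)
  spec <- synthetic_spec(planted = list(weak, strong), seed = 1)
  tm <- truth_manifest(spec)
  expect_false(tm$null_structure)
  expect_equal(length(tm$planted), 2L)
  # ordered by decreasing multiplier; expected winner is the strongest
  expect_equal(tm$planted[[1]]$risk_multiplier, 4)
  expect_equal(tm$expected_winner$values, as.list(strong$values))

  tm0 <- truth_manifest(synthetic_spec(seed = 1))
  expect_true(tm0$null_structure)
  expect_null(tm0$expected_winner)
})

test_that("covariate dependence leaves marginals intact while inducing association", {
  spec_dep <- synthetic_spec(n = 8000, seed = 6, dependence = 0.6)
  ds <- generate_children(spec_dep)
  # marginals still recovered
  obs_rural <- mean(ds$data$residence == "rural")
  expect_lt(abs(obs_rural - 0.75), 3 * sqrt(0.75 * 0.25 / 8000) + 0.01)
  # positive association between two covariates sharing the latent uniform
  tab <- table(ds$data$residence, ds$data$delivery_place)
  expect_gt(stats::chisq.test(tab)$statistic, stats::qchisq(0.999, 1))
})
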