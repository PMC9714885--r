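# two-profile fixture: profile P (v=p) with stunted mass mp, profile Q
# (v=q) with stunted mass mq, plus non-stunted records in each so the
# conditional frequencies are non-trivial
two_profile_ds <- function(mp, mq, np0 = 1, nq0 = 1) {
  haz <- c(rep(-2.5, mp + mq), rep(0, np0 + nq0))
  v <- c(rep("p", mp), rep("q", mq), rep("p", np0), rep("q", nq0))
  make_ds(haz, covariates = list(v = v), cats = list(v = c("p", "q")))
}

test_that("a single record makes a single cell carrying its weight", {
  ds <- make_ds(haz = -2.6, weight = 2.5,
                covariates = list(v = "p"), cats = list(v = c("p", "q")))
  jm <- joint_distribution(ds, "v")
  expect_equal(nrow(jm$cells), 1L)
  expect_equal(jm$cells$g, 1L)
  expect_equal(jm$cells$mass, 2.5)
  expect_equal(jm$total_mass, 2.5)
})

test_that("duplicating a record doubles its cell mass", {
  ds1 <- make_ds(haz = c(-2.6, 0.5), weight = c(1.3, 1),
                 covariates = list(v = c("p", "q")), cats = list(v = c("p", "q")))
  ds2 <- make_ds(haz = c(-2.6, -2.6, 0.5), weight = c(1.3, 1.3, 1),
                 covariates = list(v = c("p", "p", "q")), cats = list(v = c("p", "q")))
  m1 <- joint_distribution(ds1, "v")$cells
  m2 <- joint_distribution(ds2, "v")$cells
  expect_equal(m2$mass[m2$v == "p" & m2$g == 1], 2 * m1$mass[m1$v == "p" & m1$g == 1])
})

test_that("joint masses equal brute-force accumulation on a synthetic fixture", {
  ds <- random_ds(101)
  subset <- codebook_variables(ds)[1:3]
  jm <- joint_distribution(ds, subset)
  oc <- oracle_cells(ds, subset)$cells
  expect_equal(sum(jm$cells$mass), sum(oc$m1) + sum(oc$m0), tolerance = 1e-12)
  for (i in seq_len(nrow(oc))) {
    sel <- rep(TRUE, nrow(jm$cells))
    for (v in subset) sel <- sel & jm$cells[[v]] == oc[[v]][i]
    expect_equal(sum(jm$cells$mass[sel & jm$cells$g == 1]), oc$m1[i], tolerance = 1e-12)
    expect_equal(sum(jm$cells$mass[sel & jm$cells$g == 0]), oc$m0[i], tolerance = 1e-12)
  }
})

test_that("conditional frequencies are ratios of cell masses and normalize", {
  # masses m(1,p)=3, m(0,p)=1 -> P(1|p)=0.75
  ds <- make_ds(haz = c(rep(-2.5, 3), 0), weight = rep(1, 4),
                covariates = list(v = rep("p", 4)), cats = list(v = c("p", "q")))
  jm <- joint_distribution(ds, "v")
  expect_equal(conditional_frequency(jm, 1, c(v = "p")), 0.75)
  expect_equal(conditional_frequency(jm, 0, c(v = "p")), 0.25)
  # only outcome 1 observed for the profile -> 1.0
  ds2 <- make_ds(haz = c(-2.5, -3.5), covariates = list(v = c("p", "p")),
                 cats = list(v = c("p", "q")))
  expect_equal(conditional_frequency(joint_distribution(ds2, "v"), 1, c(v = "p")), 1.0)
  # unobserved profile is an error
  expect_error(conditional_frequency(jm, 1, c(v = "q")), "not observed")
  # sum over g equals 1 for every observed profile
  dsr <- random_ds(55)
  jmr <- joint_distribution(dsr, codebook_variables(dsr)[1:2])
  profs <- unique(jmr$cells[, jmr$subset])
  for (i in seq_len(nrow(profs))) {
    p <- unlist(profs[i, ])
    expect_equal(conditional_frequency(jmr, 1, p) + conditional_frequency(jmr, 0, p), 1)
  }
})

test_that("coverage-rank polling on two profiles: coverage 0.75, edge 3", {
  ds <- two_profile_ds(mp = 6, mq = 2)
  pr <- poll(joint_distribution(ds, "v"), convention = "coverage-rank", min_cell = 1)
  expect_equal(pr$winner[["v"]], "p")
  expect_equal(pr$coverage, 0.75)
  expect_equal(pr$edge, 3.0)
  expect_false(pr$tie)
})

test_that("symmetric masses give edge 1 with the tie flagged", {
  ds <- two_profile_ds(mp = 4, mq = 4)
  pr <- poll(joint_distribution(ds, "v"), min_cell = 1)
  expect_equal(pr$edge, 1.0)
  expect_true(pr$tie)
  expect_equal(pr$winner[["v"]], "p")  # lexicographic on coded order
})

test_that("the two conventions rank by mass and by conditional frequency respectively", {
  # profile p: stunted mass 6 of 10; profile q: stunted mass 4 of 5
  haz <- c(rep(-2.5, 6), rep(0, 4), rep(-2.5, 4), 0)
  v <- c(rep("p", 10), rep("q", 5))
  ds <- make_ds(haz, covariates = list(v = v), cats = list(v = c("p", "q")))
  jm <- joint_distribution(ds, "v")
  cov_rank <- poll(jm, convention = "coverage-rank", min_cell = 1)
  con_rank <- poll(jm, convention = "conditional-rank", min_cell = 1)
  expect_equal(cov_rank$winner[["v"]], "p")   # 6 > 4 by mass
  expect_equal(cov_rank$edge, 6 / 4)
  expect_equal(con_rank$winner[["v"]], "q")   # 0.8 > 0.6 by P(g|c)
  expect_equal(con_rank$edge, 0.8 / 0.6)
  # coverage is always the winning share of the outcome group's mass
  expect_equal(cov_rank$coverage, 0.6)
  expect_equal(con_rank$coverage, 0.4)
})

test_that("poll matches the brute-force oracle on a 500-record fixture", {
  set.seed(202)
  ds <- random_ds(202)
  subset <- codebook_variables(ds)[1:3]
  jm <- joint_distribution(ds, subset)
  for (conv in c("coverage-rank", "conditional-rank")) {
    pr <- poll(jm, convention = conv, min_cell = 1)
    oc <- oracle_poll(ds, subset, convention = conv, min_cell = 1)
    expect_equal(pr$winner, oc$winner)
    expect_equal(pr$runner_up, oc$runner_up)
    expect_equal(pr$coverage, oc$coverage, tolerance = 1e-12)
    expect_equal(pr$edge, oc$edge, tolerance = 1e-12)
    expect_equal(pr$tie, oc$tie)
  }
})

test_that("min_cell excludes low-support winners but not the coverage denominator", {
  # profile q has P(g|c)=1 on a single record; with min_cell 2 it cannot win
  haz <- c(rep(-2.5, 5), rep(0, 5), -2.5, rep(-2.5, 2), rep(0, 2))
  v <- c(rep("p", 10), "q", rep("r", 4))
  ds <- make_ds(haz, covariates = list(v = v), cats = list(v = c("p", "q", "r")))
  jm <- joint_distribution(ds, "v")
  pr <- poll(jm, convention = "conditional-rank", min_cell = 2)
  expect_equal(pr$winner[["v"]], "p")
  # denominator still counts q's stunted mass: coverage = 5/8
  expect_equal(pr$coverage, 5 / 8)
})

test_that("fewer than two qualifying profiles raises the insufficient-support signal", {
  ds <- make_ds(haz = c(-2.5, 0), covariates = list(v = c("p", "q")),
                cats = list(v = c("p", "q")))
  jm <- joint_distribution(ds, "v")
  expect_error(poll(jm, min_cell = 1),
               class = "profilepoll_insufficient_support")
})

test_that("polling statistics are invariant to record order and weight scale", {
  ds <- random_ds(303)
  subset <- codebook_variables(ds)[1:4]
  base <- poll(joint_distribution(ds, subset), min_cell = 1)
  set.seed(8); idx <- sample(nrow(ds$data))
  perm <- ds; perm$data <- perm$data[idx, ]
  scaled <- ds; scaled$data$weight <- ds$data$weight * 0.004812
  for (alt_ds in list(perm, scaled)) {
    alt <- poll(joint_distribution(alt_ds, subset), min_cell = 1)
    expect_equal(alt$winner, base$winner)
    expect_equal(alt$runner_up, base$runner_up)
    expect_equal(alt$coverage, base$coverage, tolerance = 1e-12)
    expect_equal(alt$edge, base$edge, tolerance = 1e-12)
  }
})

test_that("the coverage-rank winner converges to a dominant planted profile", {
  planted <- default_planted_profile(3)
  hits <- 0L
  for (seed in 1:20) {
    spec <- synthetic_spec(n = 20000, planted = list(planted), seed = seed)
    ds <- generate_children(spec)
    jm <- joint_distribution(ds, names(planted$values))
    pr <- poll(jm, convention = "coverage-rank")
    hits <- hits + all(pr$winner[names(planted$values)] == planted$values)
  }
  expect_gte(hits, 19L)  # >= 95% recovery over 20 seeds
})
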