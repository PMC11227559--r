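test_that("Fisher's method matches hand-computed values and identities", {
  f <- fisher_merge(make_scores(c(0.05, 0.05), n_datasets = 2))
  expect_equal(f$table$score, -2 * (log(0.05) + log(0.05)))
  expect_equal(f$table$score, 11.98293, tolerance = 1e-6)
  expect_equal(f$table$merged_p, 0.0174787, tolerance = 1e-5)

  none <- fisher_merge(make_scores(c(1, 1), n_datasets = 2))
  expect_identical(none$table$score, 0)
  expect_identical(none$table$merged_p, 1)

  # single dataset: the identity map on P-values
  p <- make_scores(c(0.8, 0.05, 1e-4, 0.31), n_datasets = 1)
  expect_equal(fisher_merge(p)$table$merged_p, unname(p[, 1]))
})

test_that("Brown parameter estimation recovers the covariance limits", {
  set.seed(7)
  u <- runif(10000)
  dup <- make_scores(c(u, u))
  bp <- estimate_brown_parameters(dup)
  expect_equal(bp$expected_X, 4)
  expect_equal(bp$c, 2, tolerance = 0.02)
  expect_equal(bp$k_prime, 2, tolerance = 0.02)
  # self-consistency of the scaled chi-square parameterisation
  expect_equal(bp$c, bp$var_X / (2 * bp$expected_X))
  expect_equal(bp$k_prime, 2 * bp$expected_X^2 / bp$var_X)

  ind <- make_scores(c(u, runif(10000)))
  bi <- estimate_brown_parameters(ind)
  expect_equal(bi$c, 1, tolerance = 0.05)
  expect_equal(bi$k_prime, 4, tolerance = 0.05)

  single <- make_scores(u, n_datasets = 1)
  bs <- estimate_brown_parameters(single)
  expect_equal(bs$c, 1, tolerance = 0.05)
  expect_equal(bs$k_prime, 2, tolerance = 0.05)

  expect_error(estimate_brown_parameters(make_scores(c(0.5, 0.5),
                                                     n_datasets = 2)),
               "at least 2 genes")
})

test_that("Brown merging of duplicated columns recovers the input P-values", {
  set.seed(11)
  u <- runif(10000)
  bm <- brown_merge(make_scores(c(u, u)))
  expect_equal(bm$table$merged_p, u, tolerance = 0.02)

  m <- make_scores(runif(20), n_datasets = 2)
  m[1, ] <- 1  # no evidence anywhere: merged P stays 1
  expect_identical(brown_merge(m)$table$merged_p[1], 1)
})

test_that("Brown merging is calibrated on independent uniform inputs", {
  set.seed(3)
  m <- make_scores(runif(20000))
  bm <- brown_merge(m)
  expect_equal(mean(bm$table$merged_p < 0.05), 0.05, tolerance = 0.2)
  # merged P-values are themselves roughly uniform
  expect_equal(mean(bm$table$merged_p < 0.2), 0.2, tolerance = 0.15)
})

test_that("dpm_score matches its worked examples and the literal oracle", {
  # full agreement reduces to Fisher's score
  expect_equal(dpm_score(c(0.05, 0.05), c(1, -1), c(1, -1)),
               -2 * 2 * log(0.05))
  # equal-magnitude conflict cancels completely
  expect_identical(dpm_score(c(0.05, 0.05), c(1, 1), c(1, -1)), 0)
  expect_equal(dpm_score(c(0.01, 0.5), c(1, 1), c(1, -1)),
               2 * abs(log(0.01) - log(0.5)))
  expect_equal(dpm_score(c(0.01, 0.5), c(1, 1), c(1, -1)), 7.824046,
               tolerance = 1e-6)
  expect_error(dpm_score(c(0.1, 0.2), c(1, 1, 1), c(1, 1)), "equal lengths")

  set.seed(99)
  for (rep in 1:1000) {
    k <- sample(1:5, 1)
    p <- runif(k)
    o <- sample(c(-1, 0, 1), k, replace = TRUE)
    e <- sample(c(-1, 0, 1), k, replace = TRUE)
    o[e == 0] <- 0
    expect_equal(suppressWarnings(dpm_score(p, o, e)),
                 oracle_dpm_score(p, o, e), tolerance = 1e-12)
  }
})

test_that("DPM reduces to Brown under full agreement and all-zero CV", {
  set.seed(21)
  p <- make_scores(runif(600), n_datasets = 3)
  d <- array(1, dim(p), dimnames = dimnames(p))

  # all-zero CV: every dataset directionless, identical to Brown
  dd <- dpm_merge(p, d * 0, cv = c(0, 0, 0))
  bb <- brown_merge(p)
  expect_equal(dd$table$merged_p, bb$table$merged_p)
  expect_equal(dd$table$score, bb$table$score)

  # full agreement with the CV: exact reduction to Brown
  cv <- c(1, -1, 1)
  agree <- sweep(d, 2, cv, `*`)  # o_i = e_i so o_i * e_i = +1 everywhere
  da <- dpm_merge(p, agree, cv = cv)
  expect_equal(da$table$score, bb$table$score)
  expect_equal(da$table$merged_p, bb$table$merged_p)
})

test_that("DPM is globally sign invariant in the CV and the directions", {
  set.seed(22)
  p <- make_scores(runif(400), n_datasets = 2)
  d <- make_scores(sample(c(-1, 1), 400, replace = TRUE))
  cv <- c(1, -1)
  a <- dpm_merge(p, d, cv)
  b <- dpm_merge(p, d, -cv)
  expect_identical(a$table$merged_p, b$table$merged_p)
  flipped <- dpm_merge(p, -d, cv)
  expect_identical(a$table$merged_p, flipped$table$merged_p)
})

test_that("directional conflicts never increase the score beyond Brown's", {
  set.seed(23)
  p <- make_scores(runif(1000), n_datasets = 2)
  d <- make_scores(sample(c(-1, 1), 1000, replace = TRUE))
  params <- estimate_brown_parameters(p)
  dpm <- dpm_merge(p, d, cv = c(1, 1), parameters = params)
  brown <- brown_merge(p, parameters = params)
  expect_true(all(dpm$table$score <= brown$table$score + 1e-12))
  expect_true(all(dpm$table$merged_p >= brown$table$merged_p - 1e-12))
})

test_that("degenerate covariance falls back to independence parameters", {
  # two genes with perfectly anti-correlated columns: estimated Var[X] = 0
  m <- make_scores(c(0.1, 0.9, 0.9, 0.1), n_datasets = 2)
  expect_warning(bp <- estimate_brown_parameters(m), "independence")
  expect_identical(bp$c, 1)
  expect_identical(bp$k_prime, 4)
})

test_that("directional Stouffer matches its worked examples", {
  s <- stouffer_directional_merge(make_scores(c(0.05, 0.05), n_datasets = 2),
                                  make_scores(c(1, 1)), cv = c(1, 1))
  expect_equal(s$table$score, 2 * qnorm(0.025) / sqrt(2))
  expect_equal(s$table$score, -2.771808, tolerance = 1e-6)
  expect_equal(s$table$merged_p, 0.005574597, tolerance = 1e-6)

  cancel <- stouffer_directional_merge(
    make_scores(c(0.05, 0.05), n_datasets = 2),
    make_scores(c(1, -1)), cv = c(1, 1))
  expect_identical(cancel$table$score, 0)
  expect_identical(cancel$table$merged_p, 1)

  # single dataset: identity map
  p <- make_scores(c(0.3, 0.05, 1e-5, 0.99), n_datasets = 1)
  d <- make_scores(rep(1, 4), n_datasets = 1)
  s1 <- stouffer_directional_merge(p, d, cv = 1)
  expect_equal(s1$table$merged_p, unname(p[, 1]))
})

test_that("directional Strube agrees with Stouffer for independent inputs", {
  one <- strube_directional_merge(
    make_scores(c(0.05, 0.05), n_datasets = 2),
    make_scores(c(1, 1)), cv = c(1, 1), covariance_adjusted = FALSE)
  expect_equal(one$table$merged_p, 0.005574597, tolerance = 1e-6)

  set.seed(31)
  p <- make_scores(runif(4000), n_datasets = 2)
  d <- array(1, dim(p), dimnames = dimnames(p))
  strube <- strube_directional_merge(p, d, cv = c(1, 1))
  stouf <- stouffer_directional_merge(p, d, cv = c(1, 1))
  # covariance-adjusted denominators converge to sqrt(k) when independent
  expect_equal(strube$table$merged_p, stouf$table$merged_p, tolerance = 0.05)
})

test_that("Strube with an all-zero CV ignores the direction matrix", {
  set.seed(32)
  p <- make_scores(runif(200), n_datasets = 2)
  d1 <- make_scores(sample(c(-1, 1), 200, replace = TRUE))
  d2 <- make_scores(sample(c(-1, 1), 200, replace = TRUE))
  a <- suppressWarnings(strube_directional_merge(p, d1, cv = c(0, 0)))
  b <- suppressWarnings(strube_directional_merge(p, d2, cv = c(0, 0)))
  expect_identical(a$table$score, b$table$score)
})

test_that("Strube inflates significance relative to DPM on independent nulls", {
  cfg <- simulation_config(seed = 4)
  p <- simulate_pvalue_sets(cfg)
  dirs <- assign_directions(cfg)
  dpm_frac <- mean(dpm_merge(p, dirs$directions, dirs$cv)$table$merged_p < 0.05)
  strube_frac <- mean(
    strube_directional_merge(p, dirs$directions, dirs$cv)$table$merged_p < 0.05)
  expect_gt(strube_frac, dpm_frac)
})

test_that("merge_pvalues dispatches to every method", {
  p <- make_scores(runif(20), n_datasets = 2)
  d <- make_scores(rep(1, 20))
  for (m in c("fisher", "brown", "dpm", "stouffer_directional",
              "strube_directional")) {
    fit <- merge_pvalues(p, d, cv = c(1, 1), method = m)
    expect_s3_class(fit, "merged_genes")
    expect_identical(fit$method, m)
    expect_identical(fit$table$gene_id, rownames(p))
    expect_true(all(fit$table$merged_p >= 0 & fit$table$merged_p <= 1))
  }
})
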