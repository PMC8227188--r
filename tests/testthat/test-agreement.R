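make_grid <- function(values, spacing = 0.02) {
  n <- nrow(values)
  ax <- (seq_len(n) - 1) * spacing
  trt_grid(ax, ax, values, spacing)
}

test_that("dalign matches closed forms and a brute-force double loop", {
  set.seed(1)
  a <- make_grid(matrix(runif(25, 200, 300), 5))
  expect_equal(dalign(a, a), 0)
  b <- a; b$values_um <- a$values_um + 7.3
  expect_equal(dalign(a, b), 7.3)
  for (i in 1:20) {
    va <- matrix(runif(25, 200, 300), 5)
    vb <- matrix(runif(25, 200, 300), 5)
    ga <- make_grid(va); gb <- make_grid(vb)
    acc <- 0
    for (r in 1:5) for (cc in 1:5) acc <- acc + abs(va[r, cc] - vb[r, cc])
    expect_equal(dalign(ga, gb), acc / 25, tolerance = 1e-12)
  }
  wrong <- make_grid(matrix(runif(16, 200, 300), 4))
  expect_error(dalign(a, wrong), "axes")
})

test_that("undefined cells are skipped pairwise and renormalized", {
  va <- matrix(1:25 + 0, 5); vb <- va + 2
  va[1, 1] <- NA; vb[5, 5] <- NA
  expect_equal(dalign(make_grid(va), make_grid(vb)), 2)
  expect_equal(fitting_rmse(make_grid(va), make_grid(vb)), 2)
})

test_that("fitting RMSE matches closed forms and brute force", {
  set.seed(2)
  va <- matrix(runif(25, 200, 300), 5)
  ga <- make_grid(va)
  expect_equal(fitting_rmse(ga, ga), 0)
  gb <- ga; gb$values_um <- va - 4.2
  expect_equal(fitting_rmse(ga, gb), 4.2)
  vb <- matrix(runif(25, 200, 300), 5)
  acc <- 0
  for (r in 1:5) for (cc in 1:5) acc <- acc + (va[r, cc] - vb[r, cc])^2
  expect_equal(fitting_rmse(ga, make_grid(vb)), sqrt(acc / 25),
               tolerance = 1e-12)
  expect_error(fitting_rmse(ga, matrix(1, 3, 3)), "mismatch")
})

test_that("rmse dominates dalign on any pair", {
  set.seed(3)
  for (i in 1:25) {
    ga <- make_grid(matrix(runif(36, 150, 350), 6))
    gb <- make_grid(matrix(runif(36, 150, 350), 6))
    expect_gte(fitting_rmse(ga, gb), dalign(ga, gb))
  }
})

test_that("relative bias follows its sign convention", {
  expect_equal(relative_bias(250, 250), 0)
  expect_equal(relative_bias(1.1 * 250, 250), 10)
  expect_equal(relative_bias(0.802 * 320, 320), -19.8)
  expect_error(relative_bias(1, 0), "undefined")
})

test_that("ICC(2,1) matches a two-way ANOVA variance-components oracle", {
  set.seed(4)
  x <- rnorm(8, 100, 10)
  expect_equal(icc_2_1(cbind(x, x)), 1)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    subj <- rnorm(n, 0, sample(1:5, 1))
    pairs <- cbind(subj + rnorm(n), subj + rnorm(n) + runif(1, -2, 2))
    expect_equal(icc_2_1(pairs), icc_oracle(pairs), tolerance = 1e-10)
    # exchanging columns leaves the ICC unchanged
    expect_equal(icc_2_1(pairs), icc_2_1(pairs[, 2:1]), tolerance = 1e-12)
  }
  expect_error(icc_2_1(cbind(1:2, 3:4)), "at least 3")
  expect_error(icc_2_1(matrix(5, 4, 2)), "zero total variance")
})

test_that("ICC converges to the variance-component ratio on simulated data", {
  set.seed(5)
  n <- 2000
  s_subj <- 3; s_rater <- 1; s_err <- 1.5
  subj <- rnorm(n, 0, s_subj)
  # rater effects with realized between-rater variance exactly s_rater^2
  rater_eff <- c(-1, 1) * s_rater / sqrt(2)
  pairs <- cbind(subj + rater_eff[1] + rnorm(n, 0, s_err),
                 subj + rater_eff[2] + rnorm(n, 0, s_err))
  target <- s_subj^2 / (s_subj^2 + s_rater^2 + s_err^2)
  expect_lt(abs(icc_2_1(pairs) - target), 0.02)
})

test_that("the bootstrap respects the seed contract", {
  set.seed(6)
  subj <- rnorm(30, 0, 3)
  pairs <- cbind(subj + rnorm(30), subj + rnorm(30))
  ci1 <- bootstrap_ci(pairs, icc_2_1, n_resamples = 500, seed = 42)
  ci2 <- bootstrap_ci(pairs, icc_2_1, n_resamples = 500, seed = 42)
  ci3 <- bootstrap_ci(pairs, icc_2_1, n_resamples = 500, seed = 43)
  expect_identical(ci1, ci2)
  expect_false(identical(ci1, ci3))
  expect_lte(ci1[1], ci1[2])
  # constant data with the mean statistic: zero-width interval
  const <- matrix(rep(c(1, 2), each = 10), 10)
  ci0 <- bootstrap_ci(const, statistic = mean, n_resamples = 200, seed = 1)
  expect_equal(ci0[1], ci0[2])
})

test_that("bootstrap CI coverage is close to nominal", {
  # known population ICC from a two-way model with random rater effects
  s_subj <- 2; s_err <- 1
  target <- s_subj^2 / (s_subj^2 + s_err^2)
  set.seed(7)
  cover <- replicate(200, {
    subj <- rnorm(40, 0, s_subj)
    pairs <- cbind(subj + rnorm(40, 0, s_err), subj + rnorm(40, 0, s_err))
    ci <- bootstrap_ci(pairs, icc_2_1, n_resamples = 400,
                       seed = sample.int(1e6, 1))
    ci[1] <= target && target <= ci[2]
  })
  expect_gt(mean(cover), 0.95 - 0.06)
})

test_that("distribution comparisons flag shifts and pass identical groups", {
  set.seed(8)
  base <- rnorm(50)
  same <- list(a = sample(base), b = sample(base), c = sample(base))
  rep_same <- compare_distributions(same)
  expect_gt(rep_same$kruskal_p, 0.01)
  expect_true(all(rep_same$pairwise$p_value > 0.01))

  shifted <- list(a = rnorm(50), b = rnorm(50) + 10)
  rep_shift <- compare_distributions(shifted)
  expect_lt(rep_shift$pairwise$p_value[1], 1e-6)
  expect_true(rep_shift$kruskal_significant)
  expect_named(rep_shift$shapiro_p, c("a", "b"))

  expect_error(compare_distributions(list(a = rnorm(10))), "two groups")
  expect_error(compare_distributions(list(a = rnorm(10), b = 1:2)),
               "at least 3")
})
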