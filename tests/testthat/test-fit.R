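test_that("very large penalties shrink every coefficient exactly to zero", {
  d <- random_matched(30, 6, beta = c(2, 2, rep(0, 4)),
                      block_sizes = c(3, 3), seed = 1)
  f <- clr_fit(d, lambda = c(1e4, 1e4))
  expect_true(all(f$beta == 0))
  expect_equal(f$objective, 30 * log(2), tolerance = 1e-10)
  expect_false(any(f$nonzero))
})

test_that("unpenalized fit matches the conditional MLE from survival::clogit", {
  library(survival)
  d <- random_matched(60, 3, beta = c(0.8, -0.5, 0), seed = 2)
  f <- clr_fit(d, lambda = 0, tol = 1e-9, max_iter = 500)
  df <- data.frame(y = d$y, d$X, stratum = d$stratum)
  cl <- clogit(y ~ V1 + V2 + V3 + strata(stratum), data = df)
  expect_equal(unname(f$beta), unname(coef(cl)), tolerance = 1e-5)
})

test_that("penalized solutions match brute-force grid search on tiny instances", {
  for (alpha in c(1, 0.6)) {
    d <- random_matched(5, 2, beta = c(1.5, 0), seed = 3)
    lam <- c(0.8)
    f <- clr_fit(d, lambda = lam, alpha = alpha, tol = 1e-8)
    gm <- grid_minimize(d, lambda = lam, alpha = alpha, lim = 2, step = 0.01)
    expect_equal(unname(f$beta), unname(gm$beta), tolerance = 0.011)
    expect_lte(f$objective, gm$objective + 1e-6)
  }
})

test_that("objective is continuous in alpha near the lasso end", {
  d <- random_matched(40, 4, beta = c(1, 1, 0, 0), seed = 4)
  f1 <- clr_fit(d, lambda = 3, alpha = 1)
  f2 <- clr_fit(d, lambda = 3, alpha = 0.999)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-2)
  expect_equal(f1$nonzero, f2$nonzero)
})

test_that("reported objective equals the penalty-aware objective at beta", {
  d <- random_matched(25, 5, beta = c(2, 0, 0, 0, 0),
                      block_sizes = c(2, 3), seed = 5)
  f <- clr_fit(d, lambda = c(2, 4), alpha = 0.8)
  expect_equal(f$objective,
               pen_objective(f$beta, d, lambda = c(2, 4), alpha = 0.8),
               tolerance = 1e-8)
})

test_that("lambda_max brackets the birth of the first coefficient", {
  d <- random_matched(50, 8, beta = c(2, 2, rep(0, 6)),
                      block_sizes = c(4, 4), seed = 6)
  lm <- clr_lambda_max(d)
  expect_equal(sum(clr_fit(d, lambda = rep(1.001 * lm, 2))$nonzero), 0)
  expect_gt(sum(clr_fit(d, lambda = rep(0.9 * lm, 2))$nonzero), 0)
  # closed form for a single covariate on 1:1 pairs
  d1 <- random_matched(20, 1, beta = 1, seed = 7)
  expect_equal(clr_lambda_max(d1, alpha = 0.5),
               abs(sum(pair_differences(d1))) / (2 * 0.5))
})

test_that("lambda_max is zero when no covariate varies within strata", {
  X <- matrix(rep(rnorm(5), each = 2), 10, 1)
  d <- matched_data(X, rep(1:5, each = 2), rep(c(1, 0), 5), 1)
  expect_equal(clr_lambda_max(d), 0)
})

test_that("penalty vector fits equal overall-level times penalty-factor fits", {
  d <- random_matched(40, 6, beta = c(2, 0, 0, 1, 0, 0),
                      block_sizes = c(3, 3), seed = 8)
  v <- c(2.5, 5)
  f1 <- clr_fit(d, lambda = v)
  f2 <- clr_fit(d, lambda = v[1] * c(1, v[2] / v[1]))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
})

test_that("warm-started path endpoint equals the cold-started fit", {
  d <- random_matched(50, 10, beta = c(2, 2, rep(0, 8)), seed = 9)
  lm <- clr_lambda_max(d)
  grid <- exp(seq(log(lm), log(0.05 * lm), length.out = 12))
  fits <- clr_path(d, lambda_grid = grid, tol = 1e-8)
  expect_equal(sum(fits[[1]]$nonzero), 0)  # first point at lambda_max
  cold <- clr_fit(d, lambda = grid[12], tol = 1e-8)
  expect_equal(fits[[12]]$beta, cold$beta, tolerance = 1e-6)
})

test_that("support size grows weakly along a path on well-separated data", {
  d <- random_matched(80, 10, beta = c(3, 3, 3, rep(0, 7)), seed = 10)
  lm <- clr_lambda_max(d)
  grid <- exp(seq(log(lm), log(0.05 * lm), length.out = 20))
  fits <- clr_path(d, lambda_grid = grid)
  supp <- vapply(fits, function(f) sum(f$nonzero), integer(1))
  # rare local violations are possible for lasso paths; require overall growth
  expect_lte(sum(diff(supp) < 0), 2)
  expect_gt(supp[20], supp[1])
})

test_that("ridge mixing equalizes duplicated columns", {
  d0 <- random_matched(40, 2, beta = c(1.5, 0), seed = 11)
  X <- cbind(d0$X[, 1], d0$X[, 1], d0$X[, 2])
  d <- matched_data(X, d0$stratum, d0$y, 3)
  f <- clr_fit(d, lambda = 2, alpha = 0.5, tol = 1e-9)
  expect_equal(f$beta[[1]], f$beta[[2]], tolerance = 1e-5)
})

test_that("standardized fits report coefficients on the original scale", {
  d0 <- random_matched(60, 3, beta = c(1, 0, 0), seed = 12)
  X <- sweep(d0$X, 2, c(10, 1, 0.1), "*")
  d <- matched_data(X, d0$stratum, d0$y, 3)
  f <- clr_fit(d, lambda = 3, standardize = TRUE, tol = 1e-8)
  # fitting on pre-scaled columns must agree after back-transformation
  sds <- apply(X, 2, sd)
  dstd <- matched_data(sweep(X, 2, sds, "/"), d0$stratum, d0$y, 3)
  fstd <- clr_fit(dstd, lambda = 3, tol = 1e-8)
  expect_equal(unname(f$beta), unname(fstd$beta / sds), tolerance = 1e-7)
})

test_that("invalid penalties are rejected and non-convergence is flagged", {
  d <- random_matched(20, 3, seed = 13)
  expect_error(clr_fit(d, lambda = c(1, 1)), "one entry per block")
  expect_error(clr_fit(d, lambda = -1), "invalid penalty")
  expect_error(clr_fit(d, lambda = 1, alpha = 0), "invalid penalty")
  f <- clr_fit(d, lambda = 0.01, max_iter = 1, tol = 1e-12)
  expect_false(f$converged)
})
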