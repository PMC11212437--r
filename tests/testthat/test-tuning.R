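test_that("CV folds partition strata, never observations", {
  d <- random_matched(23, 3, seed = 1)
  fold <- cv_folds(d, nfolds = 5, seed = 2)
  expect_length(fold, 23)
  expect_true(all(table(fold) >= 4))
  expect_identical(fold, cv_folds(d, nfolds = 5, seed = 2))
  expect_error(cv_folds(d, nfolds = 24), "degenerate")
})

test_that("held-out conditional log-likelihood at beta = 0 is -sum log(m_s)", {
  d <- random_matched(20, 4, k = 2, seed = 3)
  fold <- cv_folds(d, nfolds = 4, seed = 1)
  held <- subset_strata(d, strata = which(fold == 1))
  expect_equal(clr_loglik(rep(0, 4), held), -held$n_strata * log(3))
  expect_lte(clr_loglik(rnorm(4), held), 0)
})

test_that("find_default_lambda returns a grid element and improves on lambda_max", {
  d <- random_matched(60, 10, beta = c(3, 3, 3, rep(0, 7)), seed = 4)
  res <- find_default_lambda(d, details = TRUE, seed = 5)
  expect_true(res$lambda %in% res$cv$lambda)
  # strong signal: held-out likelihood at the chosen level beats lambda_max
  cv_at <- function(l) res$cv$cv_loglik[res$cv$lambda == l]
  expect_gt(cv_at(res$lambda), cv_at(max(res$cv$lambda)))
})

test_that("pure-noise data prefers heavy penalization", {
  hits <- 0
  for (seed in 1:8) {
    d <- random_matched(40, 15, beta = rep(0, 15), seed = 100 + seed)
    res <- find_default_lambda(d, details = TRUE, seed = seed, nfolds = 4)
    rank_ <- which(res$cv$lambda == res$lambda)
    if (rank_ <= 3) hits <- hits + 1  # top decile-ish of a 25-point grid
  }
  expect_gte(hits, 5)
})

test_that("default_pf penalizes a noise block more than a signal block", {
  hits <- 0
  for (seed in 1:10) {
    s <- sim_setting(p1 = 10, p2 = 10, a1 = 4, a2 = 0, beta1 = 2, beta2 = 0,
                     n_pairs = 100)
    d <- simulate_matched_data(s, seed = 200 + seed)
    pf <- tryCatch(default_pf(d, seed = seed), error = function(e) NULL)
    if (is.null(pf)) next
    ok <- (2 %in% pf$excluded) || (!is.na(pf$pf[2]) && pf$pf[2] > pf$pf[1])
    if (ok) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("statistically identical blocks get comparable penalty factors", {
  pfs <- sapply(1:6, function(seed) {
    s <- sim_setting(p1 = 10, p2 = 10, a1 = 3, a2 = 3, beta1 = 2, beta2 = 2,
                     n_pairs = 150)
    d <- simulate_matched_data(s, seed = 300 + seed)
    default_pf(d, seed = seed)$pf[2]
  })
  expect_equal(mean(pfs, na.rm = TRUE), 1, tolerance = 0.5)
})

test_that("a block with all-zero tentative coefficients is flagged excluded", {
  # block 2 constant within pairs carries no conditional information
  d0 <- random_matched(30, 2, beta = c(2, 0), seed = 7)
  Xc <- matrix(rep(rnorm(30), each = 2), 60, 1)
  d <- matched_data(cbind(d0$X, Xc), d0$stratum, d0$y, c(2, 1))
  pf <- default_pf(d, seed = 1)
  expect_true(2 %in% pf$excluded)
  expect_true(is.na(pf$pf[2]))
  expect_equal(pf$pf[1], 1)
})

test_that("no-signal data raises a no-signal error", {
  X1 <- matrix(rep(rnorm(20), each = 2), 40, 1)
  X2 <- matrix(rep(rnorm(20), each = 2), 40, 1)
  d <- matched_data(cbind(X1, X2), rep(1:20, each = 2), rep(c(1, 0), 20),
                    c(1, 1))
  expect_error(default_pf(d, seed = 1), "no signal")
})

test_that("repeated runs with a fixed seed are bit-reproducible", {
  s <- sim_setting(p1 = 6, p2 = 6, a1 = 2, a2 = 0, beta1 = 2, beta2 = 0,
                   n_pairs = 60)
  d <- simulate_matched_data(s, seed = 1)
  pf1 <- default_pf(d, seed = 42, n_repeats = 2)
  pf2 <- default_pf(d, seed = 42, n_repeats = 2)
  expect_identical(pf1$pf, pf2$pf)
  expect_identical(pf1$mean_abs_coef, pf2$mean_abs_coef)
})
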