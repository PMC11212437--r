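test_that("complementary pairs have the right sizes and are disjoint", {
  subs <- subsample_complementary_pairs(200, B = 50, seed = 1)
  expect_length(subs, 100)
  expect_true(all(lengths(subs) == 100))
  for (b in 1:50)
    expect_length(intersect(subs[[2 * b - 1]], subs[[2 * b]]), 0)
})

test_that("odd stratum counts leave one stratum out of both halves", {
  subs <- subsample_complementary_pairs(5, B = 1, seed = 3)
  expect_true(all(lengths(subs) == 2))
  expect_length(intersect(subs[[1]], subs[[2]]), 0)
  expect_length(union(subs[[1]], subs[[2]]), 4)
})

test_that("subsampling is deterministic under a fixed seed", {
  expect_identical(subsample_complementary_pairs(30, B = 5, seed = 9),
                   subsample_complementary_pairs(30, B = 5, seed = 9))
  expect_error(subsample_complementary_pairs(3, B = 1), "at least 4")
})

test_that("selection probabilities are multiples of 1/(2B) in [0, 1]", {
  d <- simulate_matched_data(
    sim_setting(p1 = 5, p2 = 5, a1 = 2, a2 = 0, beta1 = 3, beta2 = 0,
                n_pairs = 40), seed = 1)
  st <- stable_clr(d, lambda_list = list(c(3, 3), c(6, 6)), B = 8, seed = 2)
  probs <- c(st$sel_prob)
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(probs * 16, round(probs * 16), tolerance = 1e-12)
  expect_equal(st$sel_prob_max, apply(st$sel_prob, 2, max))
})

test_that("penalty-vector order does not change the aggregated probabilities", {
  d <- simulate_matched_data(
    sim_setting(p1 = 4, p2 = 4, a1 = 2, a2 = 0, beta1 = 2, beta2 = 0,
                n_pairs = 30), seed = 3)
  ll <- list(c(2, 2), c(5, 5), c(9, 9))
  s1 <- stable_clr(d, ll, B = 6, seed = 4)
  s2 <- stable_clr(d, rev(ll), B = 6, seed = 4)
  expect_equal(s1$sel_prob_max, s2$sel_prob_max)
})

test_that("adding a penalty vector can only raise max selection probabilities", {
  d <- simulate_matched_data(
    sim_setting(p1 = 4, p2 = 4, a1 = 2, a2 = 0, beta1 = 2, beta2 = 0,
                n_pairs = 30), seed = 5)
  s1 <- stable_clr(d, list(c(5, 5)), B = 6, seed = 6)
  s2 <- stable_clr(d, list(c(5, 5), c(2, 2)), B = 6, seed = 6)
  expect_true(all(s2$sel_prob_max >= s1$sel_prob_max - 1e-12))
  expect_equal(s1$sel_prob_max, s1$sel_prob[1, ], ignore_attr = TRUE)
})

test_that("penalties above lambda_max on every subsample select nothing", {
  d <- random_matched(20, 6, beta = c(2, rep(0, 5)), block_sizes = c(3, 3),
                      seed = 7)
  st <- stable_clr(d, list(c(1e5, 1e5)), B = 5, seed = 8)
  expect_true(all(st$sel_prob == 0))
})

test_that("a very strong covariate is selected in nearly every subsample", {
  probs <- sapply(1:5, function(seed) {
    d <- simulate_matched_data(
      sim_setting(p1 = 5, p2 = 5, a1 = 1, a2 = 0, beta1 = 4, beta2 = 0,
                  n_pairs = 100), seed = 400 + seed)
    lam <- 0.3 * clr_lambda_max(d)
    stable_clr(d, list(rep(lam, 2)), B = 10, seed = seed)$sel_prob_max[1]
  })
  expect_true(all(probs >= 0.9))
})

test_that("parallel and serial runs agree under a fixed seed", {
  d <- simulate_matched_data(
    sim_setting(p1 = 4, p2 = 4, a1 = 2, a2 = 0, beta1 = 2, beta2 = 0,
                n_pairs = 30), seed = 9)
  ser <- stable_clr(d, list(c(3, 3)), B = 5, seed = 10, parallel = FALSE)
  par <- stable_clr(d, list(c(3, 3)), B = 5, seed = 10, parallel = TRUE,
                    cores = 2L)
  expect_equal(ser$sel_prob, par$sel_prob)
})

test_that("thresholding is inclusive and monotone", {
  res <- list(sel_prob_max = c(a = 0.56, b = 0.54, c = 0.78))
  expect_equal(select_variables(res, 0.55), c(1L, 3L), ignore_attr = TRUE)
  expect_length(select_variables(res, 1 - 1e-9), 0)
  grid <- seq(0.5, 0.95, by = 0.05)
  sets <- lapply(grid, function(th) select_variables(res, th))
  for (i in seq_along(grid)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  expect_error(select_variables(res, 1.2), "threshold")
})
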