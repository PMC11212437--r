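# Small matched datasets and independent oracles used across the suite.

# Random 1:k matched dataset with covariates drawn N(0, 1) and the case
# assigned by the conditional-logistic mechanism.
random_matched <- function(n_strata = 10, p = 3, k = 1, beta = rep(0, p),
                           block_sizes = p, seed = 1) {
  set.seed(seed)
  m <- k + 1
  X <- matrix(rnorm(n_strata * m * p), n_strata * m, p)
  eta <- as.vector(X %*% beta)
  y <- integer(n_strata * m)
  for (i in seq_len(n_strata)) {
    idx <- (i - 1) * m + seq_len(m)
    w <- exp(eta[idx] - max(eta[idx]))
    y[idx[sample.int(m, 1, prob = w)]] <- 1L
  }
  matched_data(X, rep(seq_len(n_strata), each = m), y, block_sizes)
}

# Direct (slow) conditional log-likelihood in R, independent of the C++ path.
loglik_R <- function(beta, d) {
  eta <- as.vector(d$X %*% beta)
  ll <- 0
  for (s in seq_len(d$n_strata)) {
    idx <- which(d$stratum == s)
    ll <- ll + eta[idx][d$y[idx] == 1] - log(sum(exp(eta[idx])))
  }
  ll
}

# Penalized objective on the package's convention.
pen_objective <- function(beta, d, lambda, alpha = 1) {
  lam <- lambda[d$block]
  -loglik_R(beta, d) +
    sum(lam * (alpha * abs(beta) + (1 - alpha) / 2 * beta^2))
}

# Brute-force minimizer of the penalized objective over a grid (p <= 3).
grid_minimize <- function(d, lambda, alpha = 1, lim = 3, step = 0.02) {
  p <- ncol(d$X)
  stopifnot(p <= 3)
  vals <- seq(-lim, lim, by = step)
  grid <- as.matrix(expand.grid(rep(list(vals), p)))
  obj <- apply(grid, 1, pen_objective, d = d, lambda = lambda, alpha = alpha)
  list(beta = grid[which.min(obj), ], objective = min(obj))
}

# Central finite-difference gradient.
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- rep(0, length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

write_fixture_csv <- function(dir = tempdir()) {
  path <- file.path(dir, "toy.csv")
  cfg <- file.path(dir, "toy.yaml")
  writeLines(c("pair,status,m1,m2,g1",
               "a,1,0.5,1.0,-0.2",
               "a,0,0.1,0.6,0.3",
               "b,0,-0.4,0.0,1.1",
               "b,1,0.2,-0.3,0.8"), path)
  writeLines(c("blocks: [2, 1]", "stratum_column: pair", "case_column: status"),
             cfg)
  list(data = path, config = cfg)
}
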