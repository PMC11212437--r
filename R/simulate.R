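#' Describe a two-block matched case-control simulation setting
#'
#' @param p1,p2 number of covariates in blocks 1 and 2.
#' @param a1,a2 number of active (truly nonzero-coefficient) covariates per
#'   block; actives occupy the first `a_i` columns of each block (their
#'   position is immaterial by exchangeability of the generator).
#' @param beta1,beta2 log-odds coefficient shared by the active covariates of
#'   each block.
#' @param n_pairs number of matched sets.
#' @param k_controls controls per case (1 = matched pairs).
#' @param rho within-block exchangeable correlation of the covariates
#'   (blocks are mutually independent; default 0).
#' @return list of class `sim_setting`.
#' @export
sim_setting <- function(p1, p2, a1, a2, beta1, beta2, n_pairs = 200,
                        k_controls = 1, rho = 0) {
  stopifnot(p1 >= 1, p2 >= 0, a1 <= p1, a2 <= p2, a1 >= 0, a2 >= 0,
            n_pairs >= 1, k_controls >= 1, rho >= 0, rho < 1)
  structure(list(p1 = p1, p2 = p2, a1 = a1, a2 = a2,
                 beta1 = beta1, beta2 = beta2, n_pairs = n_pairs,
                 k_controls = k_controls, rho = rho),
            class = "sim_setting")
}

#' True coefficient vector of a simulation setting
#'
#' @param setting a [sim_setting].
#' @return numeric vector of length `p1 + p2`.
#' @export
true_beta <- function(setting) {
  c(rep(setting$beta1, setting$a1), rep(0, setting$p1 - setting$a1),
    rep(setting$beta2, setting$a2), rep(0, setting$p2 - setting$a2))
}

#' Indices of active covariates of a simulation setting
#'
#' @param setting a [sim_setting].
#' @return integer vector.
#' @export
active_set <- function(setting) which(true_beta(setting) != 0)

#' The six benchmark two-block simulation settings
#'
#' Each has 2 blocks, 100 covariates, 20 active variables in total and 200
#' matched pairs; the settings differ in how dimension, actives and effect
#' size are split between the blocks.
#'
#' @return list of 6 [sim_setting] objects.
#' @export
benchmark_settings <- function() {
  par <- list(
    c(50, 50, 10, 10, 4, 4),
    c(50, 50, 3, 17, 4, 4),
    c(50, 50, 20, 0, 4, 0),
    c(20, 80, 10, 10, 4, 1),
    c(20, 80, 15, 5, 4, 4),
    c(20, 80, 5, 15, 4, 4)
  )
  lapply(par, function(v) sim_setting(v[1], v[2], v[3], v[4], v[5], v[6],
                                      n_pairs = 200))
}

#' Simulate a matched case-control dataset under the conditional-logistic model
#'
#' For each matched set, `k_controls + 1` covariate vectors are drawn from a
#' multivariate normal with zero mean, unit variances and exchangeable
#' correlation `rho` within each block (blocks independent); the case label
#' is then assigned to member `j` with probability
#' \eqn{\exp(x_j'\beta) / \sum_l \exp(x_l'\beta)} — exactly the conditional
#' logistic mechanism that the fitting functions assume, which makes
#' parameter recovery well posed. Matched confounders act as stratum effects
#' and cancel from this probability, so they are not generated explicitly.
#'
#' @param setting a [sim_setting].
#' @param seed integer seed.
#' @return a validated [matched_data] object with `n_pairs` strata of size
#'   `k_controls + 1` and block sizes `(p1, p2)`.
#' @export
#' @examples
#' d <- simulate_matched_data(benchmark_settings()[[1]], seed = 1)
#' d
simulate_matched_data <- function(setting, seed = 1) {
  stopifnot(inherits(setting, "sim_setting"))
  s <- setting
  p <- s$p1 + s$p2
  m <- s$k_controls + 1L
  n_obs <- s$n_pairs * m
  beta <- true_beta(s)
  with_seed(seed, {
    X <- matrix(rnorm(n_obs * p), n_obs, p)
    if (s$rho > 0) {
      # exchangeable within-block correlation via a shared block factor
      for (b in 1:2) {
        cols <- if (b == 1) seq_len(s$p1) else s$p1 + seq_len(s$p2)
        if (length(cols) == 0) next
        shared <- rnorm(n_obs)
        X[, cols] <- sqrt(s$rho) * shared + sqrt(1 - s$rho) * X[, cols]
      }
    }
    eta <- as.vector(X %*% beta)
    y <- integer(n_obs)
    for (i in seq_len(s$n_pairs)) {
      idx <- (i - 1L) * m + seq_len(m)
      e <- eta[idx]
      w <- exp(e - max(e))
      y[idx[sample.int(m, 1L, prob = w)]] <- 1L
    }
    bs <- c(s$p1, s$p2)
    matched_data(X, stratum = rep(seq_len(s$n_pairs), each = m), y = y,
                 block_sizes = bs[bs > 0],
                 block_names = c("block1", "block2")[bs > 0])
  })
}
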