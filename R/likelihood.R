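#' Conditional log-likelihood of a matched-design logistic model
#'
#' For coefficient vector \eqn{\beta} and linear predictors
#' \eqn{\eta_j = x_j'\beta}, the conditional likelihood of a matched set
#' \eqn{s} with a single case is
#' \eqn{\exp(\eta_{case}) / \sum_{j \in s} \exp(\eta_j)}; the function returns
#' the sum of its logarithm over strata. Stratum-specific intercepts cancel,
#' which is what makes the matched design estimable without nuisance
#' parameters. Computed with a per-stratum max subtraction so that large
#' linear predictors do not overflow.
#'
#' @param beta numeric coefficient vector, length `ncol(d$X)`.
#' @param d a [matched_data] object.
#' @return scalar conditional log-likelihood (nats); always `<= 0`.
#' @export
#' @examples
#' d <- simulate_matched_data(sim_setting(p1 = 2, p2 = 2, a1 = 1, a2 = 0,
#'                            beta1 = 1, beta2 = 0, n_pairs = 20), seed = 1)
#' clr_loglik(rep(0, 4), d)  # = -20 * log(2)
clr_loglik <- function(beta, d) {
  beta <- as.numeric(beta)
  if (length(beta) != ncol(d$X))
    stop("beta has length ", length(beta), " but data has ", ncol(d$X),
         " covariates", call. = FALSE)
  cpp_clr_loglik(d$X, beta, d$y, stratum_starts(d))
}

#' Gradient of the conditional log-likelihood
#'
#' Exact score vector: for each stratum the case's covariates minus the
#' softmax-weighted average of all members' covariates, summed over strata.
#'
#' @inheritParams clr_loglik
#' @return numeric vector of length `ncol(d$X)`.
#' @export
clr_loglik_grad <- function(beta, d) {
  beta <- as.numeric(beta)
  if (length(beta) != ncol(d$X))
    stop("beta has length ", length(beta), " but data has ", ncol(d$X),
         " covariates", call. = FALSE)
  g <- cpp_clr_grad(d$X, beta, d$y, stratum_starts(d))
  names(g) <- colnames(d$X)
  g
}
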