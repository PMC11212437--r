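#' Fit a penalized conditional logistic regression model
#'
#' Minimizes the negative conditional log-likelihood plus a block-structured
#' elastic-net penalty
#' \deqn{-\ell(\beta) + \sum_p \lambda_p \left[ \alpha \|\beta_p\|_1 +
#'       \tfrac{1-\alpha}{2} \|\beta_p\|_2^2 \right],}
#' where \eqn{\lambda_p} is the penalty level of covariate block \eqn{p} and
#' \eqn{\alpha \in (0, 1]} mixes lasso and ridge. Penalties are on the
#' "sum" scale (no \eqn{1/n} factor), so a given \eqn{\lambda} shrinks less
#' as strata accrue. The solver is an iteratively reweighted least squares
#' outer loop (diagonal curvature of the stratum softmax) around cyclic
#' coordinate descent with soft-thresholding, so zero coefficients are exact
#' zeros; a step-halving safeguard keeps the objective non-increasing.
#'
#' By default covariates enter as given: user-specified block penalties refer
#' to the data on its original scale. With `standardize = TRUE` columns are
#' scaled to unit standard deviation before fitting and coefficients are
#' returned on the original scale (the penalty then applies on the
#' standardized scale).
#'
#' @param d a [matched_data] object.
#' @param lambda positive penalty level per block (length
#'   `length(d$block_sizes)`); a scalar is recycled to all blocks. `lambda =
#'   0` (unpenalized) is permitted for small problems.
#' @param alpha elastic-net mixing parameter in `(0, 1]`; `1` = lasso.
#' @param standardize scale columns to unit SD before fitting (default off).
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change between outer iterations.
#' @param max_iter maximum number of outer iterations; non-convergence is
#'   flagged in the result, not raised.
#' @param beta_init optional warm-start coefficient vector.
#' @return An object of class `clr_fit`: list with `beta` (named), `objective`
#'   (penalized objective at `beta`), `loglik`, `n_iterations`, `converged`,
#'   `nonzero` (logical; exact zeros), `lambda`, `alpha`, `block`.
#' @export
#' @examples
#' d <- simulate_matched_data(sim_setting(p1 = 5, p2 = 5, a1 = 2, a2 = 0,
#'                            beta1 = 2, beta2 = 0, n_pairs = 50), seed = 1)
#' f <- clr_fit(d, lambda = c(5, 5))
#' which(f$nonzero)
clr_fit <- function(d, lambda, alpha = 1, standardize = FALSE,
                    tol = 1e-6, max_iter = 100, beta_init = NULL) {
  P <- length(d$block_sizes)
  if (length(lambda) == 1L) lambda <- rep(lambda, P)
  if (length(lambda) != P)
    stop("lambda must have one entry per block (", P, ")", call. = FALSE)
  if (any(lambda < 0) || any(!is.finite(lambda)))
    stop("invalid penalty: lambda must be finite and >= 0", call. = FALSE)
  if (alpha <= 0 || alpha > 1)
    stop("invalid penalty: alpha must be in (0, 1]", call. = FALSE)
  p <- ncol(d$X)
  X <- d$X
  scale_ <- rep(1, p)
  if (standardize) {
    scale_ <- apply(X, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    X <- sweep(X, 2, scale_, "/")
  }
  lam_col <- lambda[d$block]
  l1 <- alpha * lam_col
  l2 <- (1 - alpha) * lam_col
  beta_init <- if (is.null(beta_init)) rep(0, p) else as.numeric(beta_init) * scale_
  fit <- cpp_clr_fit(X, d$y, stratum_starts(d), l1, l2,
                     beta_init, tol, as.integer(max_iter))
  beta_std <- fit$beta
  beta <- beta_std / scale_
  names(beta) <- colnames(d$X)
  structure(list(
    beta = beta,
    objective = fit$objective,
    loglik = clr_loglik(beta, d),
    n_iterations = fit$n_iterations,
    converged = fit$converged,
    nonzero = beta_std != 0,
    lambda = lambda,
    alpha = alpha,
    block = d$block
  ), class = "clr_fit")
}

#' @export
print.clr_fit <- function(x, ...) {
  cat("Penalized CLR fit: lambda = (", paste(signif(x$lambda, 4), collapse = ", "),
      "), alpha =", x$alpha, "\n")
  cat("  nonzero coefficients:", sum(x$nonzero), "/", length(x$beta),
      "| objective:", format(x$objective), "| converged:", x$converged, "\n")
  invisible(x)
}

#' Smallest overall penalty level with an all-zero solution
#'
#' For penalty factors \eqn{pf} and mixing \eqn{\alpha}, returns
#' \eqn{\lambda_{max} = \max_j |g_j(0)| / (\alpha \, pf_{block(j)})}, where
#' \eqn{g(0)} is the gradient of the conditional log-likelihood at zero.
#' Any overall level at or above it makes \eqn{\beta = 0} optimal (KKT
#' condition of the lasso part).
#'
#' @param d a [matched_data] object.
#' @param pf strictly positive penalty factor per block (scalar recycled).
#' @param alpha elastic-net mixing in `(0, 1]`.
#' @return scalar `lambda_max`.
#' @export
clr_lambda_max <- function(d, pf = 1, alpha = 1) {
  P <- length(d$block_sizes)
  if (length(pf) == 1L) pf <- rep(pf, P)
  if (length(pf) != P || any(pf <= 0) || any(!is.finite(pf)))
    stop("penalty factors must be finite and > 0 for every block", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0 for lambda_max", call. = FALSE)
  g <- clr_loglik_grad(rep(0, ncol(d$X)), d)
  # tiny headroom so that refitting exactly at lambda_max cannot round a
  # boundary coordinate to a nonzero value
  max(abs(g) / (alpha * pf[d$block])) * (1 + 1e-10)
}

#' Regularization path with warm starts
#'
#' Fits the penalized model along a decreasing grid of overall penalty
#' levels, the block penalty vector at grid value \eqn{g} being
#' \eqn{g \cdot (pf_1, \ldots, pf_P)}. Each fit is warm-started from the
#' previous one.
#'
#' @inheritParams clr_lambda_max
#' @param lambda_grid strictly decreasing positive overall penalty levels.
#' @param ... passed to [clr_fit()] (`standardize`, `tol`, `max_iter`).
#' @return list of `clr_fit` objects, one per grid value.
#' @export
clr_path <- function(d, pf = 1, alpha = 1, lambda_grid, ...) {
  if (length(lambda_grid) > 1L && any(diff(lambda_grid) >= 0))
    stop("lambda_grid must be strictly decreasing", call. = FALSE)
  P <- length(d$block_sizes)
  if (length(pf) == 1L) pf <- rep(pf, P)
  fits <- vector("list", length(lambda_grid))
  beta <- rep(0, ncol(d$X))
  for (g in seq_along(lambda_grid)) {
    fits[[g]] <- clr_fit(d, lambda = lambda_grid[g] * pf, alpha = alpha,
                         beta_init = beta, ...)
    beta <- fits[[g]]$beta
  }
  fits
}

#' Write fitted coefficients to a TSV file
#'
#' @param fit a `clr_fit` object.
#' @param file output path; columns `variable`, `block`, `beta`, `nonzero`.
#' @return `file`, invisibly.
#' @export
write_coefficients <- function(fit, file) {
  tab <- data.frame(variable = names(fit$beta), block = fit$block,
                    beta = fit$beta, nonzero = as.integer(fit$nonzero))
  utils::write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
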