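#' Cross-validation folds that never split a matched set
#'
#' Strata (not observations) are shuffled and dealt round-robin into
#' `nfolds` folds, so each matched set appears in exactly one fold.
#'
#' @param d a [matched_data] object.
#' @param nfolds number of folds (>= 2, <= number of strata).
#' @param seed integer seed for the shuffle.
#' @return integer vector of fold ids, one per stratum.
#' @export
cv_folds <- function(d, nfolds = 5, seed = 1) {
  if (nfolds < 2) stop("nfolds must be >= 2", call. = FALSE)
  if (nfolds > d$n_strata)
    stop("degenerate CV folds: more folds than strata", call. = FALSE)
  perm <- with_seed(seed, sample.int(d$n_strata))
  fold <- integer(d$n_strata)
  fold[perm] <- rep_len(seq_len(nfolds), d$n_strata)
  fold
}

# Run expr under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Log-spaced overall-penalty grid from lambda_max down to ratio * lambda_max.
lambda_grid <- function(lmax, grid_size = 25, min_ratio = 1e-3) {
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = grid_size))
}

#' Cross-validated conditional log-likelihood over a penalty grid
#'
#' For each overall penalty level in the grid, fits the model on the training
#' strata of each fold (with warm starts along the grid) and evaluates the
#' conditional log-likelihood on the held-out strata; held-out contributions
#' are summed over folds.
#'
#' @inheritParams clr_lambda_max
#' @param grid decreasing positive overall penalty levels.
#' @param nfolds number of CV folds.
#' @param seed seed for the fold shuffle.
#' @param ... passed to [clr_fit()].
#' @return data.frame with columns `lambda` and `cv_loglik`.
#' @export
cv_loglik <- function(d, pf = 1, alpha = 1, grid, nfolds = 5, seed = 1, ...) {
  P <- length(d$block_sizes)
  if (length(pf) == 1L) pf <- rep(pf, P)
  fold <- cv_folds(d, nfolds, seed)
  cv <- numeric(length(grid))
  for (k in seq_len(nfolds)) {
    train <- subset_strata(d, strata = which(fold != k))
    test <- subset_strata(d, strata = which(fold == k))
    fits <- clr_path(train, pf = pf, alpha = alpha, lambda_grid = grid, ...)
    cv <- cv + vapply(fits, function(f) clr_loglik(f$beta, test), numeric(1))
  }
  data.frame(lambda = grid, cv_loglik = cv)
}

#' Data-adaptive penalty level by cross-validated conditional log-likelihood
#'
#' Builds a log-spaced grid of `grid_size` overall penalty levels from
#' \eqn{\lambda_{max}} (computed for the given penalty factors) down to
#' `min_ratio` times it, and returns the grid value maximizing the summed
#' held-out conditional log-likelihood over matched-set-stratified folds.
#'
#' @inheritParams cv_loglik
#' @param pf penalty factors, e.g. from [default_pf()]; positive per block.
#' @param grid_size number of grid points.
#' @param min_ratio smallest grid value as a fraction of `lambda_max`.
#' @param details if `TRUE`, also return the CV curve.
#' @return the selected overall penalty level (scalar), or, with
#'   `details = TRUE`, a list with `lambda` and the CV curve `cv`.
#' @export
find_default_lambda <- function(d, pf = 1, alpha = 1, nfolds = 5,
                                grid_size = 25, min_ratio = 0.01, seed = 1,
                                details = FALSE, ...) {
  lmax <- clr_lambda_max(d, pf = pf, alpha = alpha)
  if (lmax <= 0)
    stop("lambda_max is zero: no covariate varies within strata", call. = FALSE)
  grid <- lambda_grid(lmax, grid_size, min_ratio)
  curve <- cv_loglik(d, pf = pf, alpha = alpha, grid = grid,
                     nfolds = nfolds, seed = seed, ...)
  lam <- grid[which.max(curve$cv_loglik)]
  if (details) list(lambda = lam, cv = curve) else lam
}

#' Data-adaptive penalty factors from tentative model fits
#'
#' Implements the heuristic of fitting tentative penalized conditional
#' logistic models and setting each block's relative penalty inversely
#' proportional to the mean absolute estimated coefficient of that block:
#' blocks whose tentative coefficients are larger are penalized less. With
#' `type_step1 = "separate"` one tentative model is fitted per block (using
#' only that block's covariates); with `"joint"` a single model with equal
#' penalty factors covers all blocks. In both cases the tentative model's
#' overall penalty level is chosen by cross-validated conditional
#' log-likelihood.
#'
#' The mean is taken over the absolute values of all coefficients of the
#' block, zeros included. A block whose tentative coefficients are all zero
#' carries no detectable signal and is flagged for exclusion; penalty factors
#' are normalized so the first non-excluded block has factor 1. Because the
#' tentative penalty is chosen by cross-validation, results vary with the
#' fold shuffle; `n_repeats > 1` averages the penalty factors over repeated
#' runs (a block is excluded if it is excluded in more than half of them).
#'
#' @param d a [matched_data] object with at least 2 blocks.
#' @param alpha elastic-net mixing used for the tentative model(s).
#' @param type_step1 `"separate"` (one tentative model per block) or
#'   `"joint"` (a single model over all blocks).
#' @param nfolds CV folds for the tentative penalty level.
#' @param n_repeats number of repeated runs to average over.
#' @param seed integer seed; repeat r uses `seed + r - 1`.
#' @param ... passed to [clr_fit()].
#' @return list of class `clr_pf`: `pf` (penalty factor per block, `NA` for
#'   excluded blocks), `excluded` (integer block indices), `mean_abs_coef`
#'   (per repeat x block), `type_step1`.
#' @export
default_pf <- function(d, alpha = 1, type_step1 = c("separate", "joint"),
                       nfolds = 5, n_repeats = 1, seed = 1, ...) {
  type_step1 <- match.arg(type_step1)
  P <- length(d$block_sizes)
  if (P < 2) stop("default_pf requires at least 2 blocks", call. = FALSE)

  m_mat <- matrix(NA_real_, n_repeats, P)
  for (r in seq_len(n_repeats)) {
    seed_r <- seed + r - 1
    if (type_step1 == "separate") {
      for (b in seq_len(P)) {
        cols <- which(d$block == b)
        db <- subset_strata(d, columns = cols)
        lam <- tryCatch(
          find_default_lambda(db, pf = 1, alpha = alpha, nfolds = nfolds,
                              seed = seed_r, ...),
          error = function(e) NA_real_)
        m_mat[r, b] <- if (is.na(lam)) 0 else
          mean(abs(clr_fit(db, lambda = lam, alpha = alpha, ...)$beta))
      }
    } else {
      lam <- find_default_lambda(d, pf = rep(1, P), alpha = alpha,
                                 nfolds = nfolds, seed = seed_r, ...)
      fit <- clr_fit(d, lambda = rep(lam, P), alpha = alpha, ...)
      for (b in seq_len(P))
        m_mat[r, b] <- mean(abs(fit$beta[d$block == b]))
    }
  }

  pf_mat <- matrix(NA_real_, n_repeats, P)
  for (r in seq_len(n_repeats)) {
    m <- m_mat[r, ]
    if (all(m == 0)) next
    ref <- which(m > 0)[1L]
    pf_mat[r, m > 0] <- m[ref] / m[m > 0]
  }
  if (all(is.na(pf_mat)))
    stop("no signal detected: all blocks have zero tentative coefficients",
         call. = FALSE)
  n_excl <- colSums(is.na(pf_mat))
  excluded <- which(n_excl > n_repeats / 2)
  pf <- colMeans(pf_mat, na.rm = TRUE)
  pf[excluded] <- NA_real_
  keep <- which(!is.na(pf))
  pf[keep] <- pf[keep] / pf[keep[1L]]

  structure(list(pf = pf, excluded = excluded, mean_abs_coef = m_mat,
                 type_step1 = type_step1),
            class = "clr_pf")
}

#' @export
print.clr_pf <- function(x, ...) {
  cat("Data-adaptive penalty factors (", x$type_step1, "): (",
      paste(signif(x$pf, 3), collapse = ", "), ")\n", sep = "")
  if (length(x$excluded))
    cat("  blocks flagged for exclusion:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
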