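#' Complementary-pairs subsamples of matched sets
#'
#' Draws `B` independent random partitions of the strata; each partition
#' contributes two disjoint half-samples of exactly `floor(n/2)` strata
#' (when `n` is odd, one stratum per partition belongs to neither half).
#' Subsampling acts on whole matched sets, never on individual observations.
#'
#' @param n_strata number of matched sets (>= 4).
#' @param B number of complementary pairs (>= 1); yields `2B` subsamples.
#' @param seed integer seed; fixed seed gives identical subsamples.
#' @return list of `2B` integer vectors of stratum ids; elements `2b - 1`
#'   and `2b` are disjoint.
#' @export
subsample_complementary_pairs <- function(n_strata, B = 100, seed = 1) {
  if (n_strata < 4) stop("need at least 4 strata to subsample", call. = FALSE)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  h <- n_strata %/% 2L
  with_seed(seed, {
    out <- vector("list", 2L * B)
    for (b in seq_len(B)) {
      perm <- sample.int(n_strata)
      out[[2L * b - 1L]] <- sort(perm[seq_len(h)])
      out[[2L * b]] <- sort(perm[h + seq_len(h)])
    }
    out
  })
}

#' Stability selection for penalized conditional logistic regression
#'
#' Complementary-pairs stability selection over a list of candidate
#' per-block penalty vectors. For every penalty vector and every one of the
#' `2B` half-samples of matched sets, a penalized conditional logistic model
#' is fitted; a variable's selection probability under that vector is the
#' fraction of the `2B` fits in which its coefficient is exactly nonzero,
#' and its overall selection probability is the maximum over the candidate
#' vectors. Subsamples are drawn once and shared by all penalty vectors, so
#' differences between vectors are not confounded with subsampling noise.
#'
#' A fit that fails to converge within its iteration budget is counted as
#' selecting nothing on that half-sample (conservative) and tallied in
#' `n_nonconverged`. With `parallel = TRUE` half-sample fits are dispatched
#' with [parallel::mclapply()]; subsamples are generated before dispatch, so
#' results are identical to a serial run with the same seed.
#'
#' @param d a [matched_data] object.
#' @param lambda_list list of numeric penalty vectors, each of length
#'   `length(d$block_sizes)` (a single vector may be passed directly).
#' @param alpha elastic-net mixing in `(0, 1]`.
#' @param B number of complementary pairs (default 100, i.e. 200 fits per
#'   penalty vector).
#' @param seed integer seed for the subsample draw.
#' @param parallel dispatch subsample fits over `cores` workers.
#' @param cores number of workers when `parallel = TRUE`.
#' @param ... passed to [clr_fit()] (`standardize`, `tol`, `max_iter`).
#' @return An object of class `clr_stability`: `sel_prob` (matrix, penalty
#'   vectors x variables), `sel_prob_max` (named vector, componentwise max),
#'   `B`, `lambda_list`, `seed`, `n_nonconverged`, `block`.
#' @export
#' @examples
#' d <- simulate_matched_data(sim_setting(p1 = 5, p2 = 5, a1 = 2, a2 = 0,
#'                            beta1 = 3, beta2 = 0, n_pairs = 40), seed = 1)
#' s <- stable_clr(d, lambda_list = list(c(4, 4), c(8, 8)), B = 10, seed = 2)
#' select_variables(s, 0.6)
stable_clr <- function(d, lambda_list, alpha = 1, B = 100, seed = 1,
                       parallel = FALSE, cores = 2L, ...) {
  if (!is.list(lambda_list)) lambda_list <- list(lambda_list)
  P <- length(d$block_sizes)
  for (v in lambda_list)
    if (length(v) != P)
      stop("each penalty vector must have one entry per block (", P, ")",
           call. = FALSE)
  subs <- subsample_complementary_pairs(d$n_strata, B = B, seed = seed)
  p <- ncol(d$X)

  # fit the most-penalized vector first and warm-start the rest from it
  vec_order <- order(vapply(lambda_list, sum, numeric(1)), decreasing = TRUE)
  one_subsample <- function(strata) {
    ds <- subset_strata(d, strata = strata)
    sel <- matrix(FALSE, p, length(lambda_list))
    nconv <- 0L
    binit <- NULL
    for (v in vec_order) {
      f <- clr_fit(ds, lambda = lambda_list[[v]], alpha = alpha,
                   beta_init = binit, ...)
      binit <- f$beta
      if (f$converged) sel[, v] <- f$nonzero else nconv <- nconv + 1L
    }
    list(sel = sel, nconv = nconv)
  }

  res <- if (parallel) {
    parallel::mclapply(subs, one_subsample, mc.cores = cores)
  } else {
    lapply(subs, one_subsample)
  }
  counts <- matrix(0, length(lambda_list), p)
  nonconv <- 0L
  for (s in seq_along(res)) {
    counts <- counts + t(res[[s]]$sel)
    nonconv <- nonconv + res[[s]]$nconv
  }
  sel_prob <- counts / (2 * B)
  colnames(sel_prob) <- colnames(d$X)
  sel_prob_max <- apply(sel_prob, 2, max)

  structure(list(sel_prob = sel_prob, sel_prob_max = sel_prob_max,
                 B = B, lambda_list = lambda_list, seed = seed,
                 alpha = alpha, block = d$block, n_nonconverged = nonconv),
            class = "clr_stability")
}

#' Threshold stability-selection probabilities
#'
#' Returns the indices of variables whose maximum selection probability is at
#' or above the threshold (inclusive comparison, so a variable exactly at the
#' threshold is selected). Typical thresholds lie in 0.55-0.9.
#'
#' @param result a `clr_stability` object (or any object with a
#'   `sel_prob_max` element).
#' @param threshold scalar in `(0, 1)`.
#' @return integer vector of selected variable indices.
#' @export
select_variables <- function(result, threshold = 0.55) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  which(result$sel_prob_max >= threshold)
}

#' @export
print.clr_stability <- function(x, ...) {
  cat("Stability selection: B =", x$B, "(", 2 * x$B, "half-sample fits ) x",
      length(x$lambda_list), "penalty vector(s)\n")
  cat("  variables with max selection probability >= 0.55:",
      sum(x$sel_prob_max >= 0.55), "/", length(x$sel_prob_max), "\n")
  invisible(x)
}

#' Write selection probabilities to a TSV file
#'
#' @param result a `clr_stability` object.
#' @param file output path; columns `variable`, `block`, one probability
#'   column per penalty vector, `max_prob` and `selected`.
#' @param threshold selection threshold used for the `selected` column.
#' @return `file`, invisibly.
#' @export
write_selection <- function(result, file, threshold = 0.55) {
  probs <- t(result$sel_prob)
  colnames(probs) <- paste0("prob_lambda", seq_along(result$lambda_list))
  tab <- data.frame(variable = names(result$sel_prob_max),
                    block = result$block, probs,
                    max_prob = result$sel_prob_max,
                    selected = as.integer(result$sel_prob_max >= threshold))
  utils::write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
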