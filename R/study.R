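#' Power and false discovery rate of a collection of selections
#'
#' Power is the average over datasets of the proportion of active variables
#' selected; FDR is the average proportion of inactive variables among the
#' selected ones, a dataset with no selections contributing 0.
#'
#' @param selected list of integer vectors (selected variable indices per
#'   dataset).
#' @param active integer vector of truly active variable indices.
#' @return list with `power`, `fdr`, per-dataset vectors `power_i`, `fdr_i`,
#'   and Monte-Carlo standard errors `power_se`, `fdr_se`.
#' @export
eval_selection <- function(selected, active) {
  n_active <- length(active)
  power_i <- vapply(selected, function(s) {
    if (n_active == 0) NA_real_ else length(intersect(s, active)) / n_active
  }, numeric(1))
  fdr_i <- vapply(selected, function(s) {
    length(setdiff(s, active)) / max(length(s), 1)
  }, numeric(1))
  mcse <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  list(power = mean(power_i), fdr = mean(fdr_i),
       power_i = power_i, fdr_i = fdr_i,
       power_se = mcse(power_i), fdr_se = mcse(fdr_i))
}

# Candidate penalty vectors: the tuned vector lambda * pf scaled by each
# factor. The study harness uses the tuned vector alone (factors = 1);
# a spread such as c(0.5, 1, 2) widens the search around it.
build_lambda_list <- function(lambda, pf, factors = 1) {
  lapply(factors, function(f) f * lambda * pf)
}

# Full per-dataset pipeline: tune penalty factors, tune the overall level,
# run stability selection. Blocks flagged for exclusion by default_pf are
# dropped before tuning/stability; their variables get selection
# probability 0. Returns sel_prob_max on the full variable indexing.
pipeline_one <- function(d, alpha = 1, B = 50, nfolds = 5, seed = 1,
                         lambda_factors = 1, type_step1 = "separate",
                         parallel = FALSE, cores = 2L) {
  p <- ncol(d$X)
  sel_prob_max <- stats::setNames(rep(0, p), colnames(d$X))
  pf_fit <- tryCatch(
    default_pf(d, alpha = alpha, type_step1 = type_step1, nfolds = nfolds,
               seed = seed),
    error = function(e) NULL)
  if (is.null(pf_fit))    # no signal in any block: nothing can be selected
    return(list(sel_prob_max = sel_prob_max, pf = NULL, lambda = NA_real_))
  keep_blocks <- setdiff(seq_along(d$block_sizes), pf_fit$excluded)
  cols <- which(d$block %in% keep_blocks)
  dk <- if (length(pf_fit$excluded)) subset_strata(d, columns = cols) else d
  pf <- pf_fit$pf[keep_blocks]
  lam <- find_default_lambda(dk, pf = pf, alpha = alpha, nfolds = nfolds,
                             seed = seed)
  st <- stable_clr(dk, lambda_list = build_lambda_list(lam, pf, lambda_factors),
                   alpha = alpha, B = B, seed = seed,
                   parallel = parallel, cores = cores)
  sel_prob_max[cols] <- st$sel_prob_max
  list(sel_prob_max = sel_prob_max, pf = pf_fit, lambda = lam)
}

#' Run the full selection pipeline over replicated simulated datasets
#'
#' For each of `n_datasets` datasets simulated from `setting`, computes
#' data-adaptive penalty factors, tunes the overall penalty level by
#' cross-validated conditional log-likelihood, runs complementary-pairs
#' stability selection with the tuned penalty vector (optionally also its
#' multiples, see `lambda_factors`), and
#' selects variables at `threshold`; power and FDR are averaged over
#' datasets. Per-dataset maximum selection probabilities are kept so other
#' thresholds can be evaluated afterwards without refitting
#' (see [threshold_sweep()]).
#'
#' @param setting a [sim_setting].
#' @param n_datasets number of simulated datasets.
#' @param B complementary pairs per stability-selection run.
#' @param threshold selection-probability threshold.
#' @param alpha elastic-net mixing.
#' @param seed master seed; dataset `i` is generated with `seed + i - 1`.
#' @param nfolds CV folds for both tuning steps.
#' @param lambda_factors multipliers of the tuned penalty vector that form
#'   the stability-selection candidate list; the default uses the tuned
#'   vector alone.
#' @param type_step1 tentative-model mode for [default_pf()].
#' @param parallel,cores forwarded to [stable_clr()].
#' @return list of class `clr_eval`: `power`, `fdr`, `power_se`, `fdr_se`,
#'   `n_datasets`, `threshold`, `selected` (list), `sel_prob` (matrix,
#'   datasets x variables), `active`, `setting`.
#' @export
run_setting <- function(setting, n_datasets = 100, B = 50, threshold = 0.55,
                        alpha = 1, seed = 1, nfolds = 5,
                        lambda_factors = 1,
                        type_step1 = "separate",
                        parallel = FALSE, cores = 2L) {
  active <- active_set(setting)
  p <- setting$p1 + setting$p2
  sp <- matrix(NA_real_, n_datasets, p)
  for (i in seq_len(n_datasets)) {
    di <- simulate_matched_data(setting, seed = seed + i - 1)
    res <- pipeline_one(di, alpha = alpha, B = B, nfolds = nfolds,
                        seed = seed + i - 1, lambda_factors = lambda_factors,
                        type_step1 = type_step1,
                        parallel = parallel, cores = cores)
    sp[i, ] <- res$sel_prob_max
  }
  selected <- apply(sp, 1, function(x) which(x >= threshold), simplify = FALSE)
  ev <- eval_selection(selected, active)
  structure(c(ev[c("power", "fdr", "power_se", "fdr_se")],
              list(n_datasets = n_datasets, threshold = threshold,
                   selected = selected, sel_prob = sp, active = active,
                   setting = setting, seed = seed, B = B, alpha = alpha)),
            class = "clr_eval")
}

#' @export
print.clr_eval <- function(x, ...) {
  cat(sprintf("Selection study: %d datasets, B = %d, threshold = %.2f\n",
              x$n_datasets, x$B, x$threshold))
  cat(sprintf("  power = %.3f (SE %.3f), FDR = %.3f (SE %.3f)\n",
              x$power, x$power_se, x$fdr, x$fdr_se))
  invisible(x)
}

#' Re-threshold stored stability results over a grid of thresholds
#'
#' Uses the per-dataset maximum selection probabilities of a [run_setting()]
#' result to compute power and FDR at each threshold without refitting.
#' Selected sets are nested as the threshold grows, so power and FDR are
#' monotone summaries of the same fits.
#'
#' @param result a `clr_eval` object from [run_setting()].
#' @param thresholds numeric vector of thresholds in `(0, 1)`.
#' @return data.frame with columns `threshold`, `power`, `fdr`.
#' @export
threshold_sweep <- function(result, thresholds = seq(0.55, 0.9, by = 0.05)) {
  out <- lapply(thresholds, function(th) {
    selected <- apply(result$sel_prob, 1, function(x) which(x >= th),
                      simplify = FALSE)
    ev <- eval_selection(selected, result$active)
    data.frame(threshold = th, power = ev$power, fdr = ev$fdr)
  })
  do.call(rbind, out)
}

#' Power and FDR of the pipeline across sample sizes
#'
#' Re-runs [run_setting()] with the same setting at each number of matched
#' pairs in `sizes`.
#'
#' @param setting a [sim_setting]; its `n_pairs` is overridden per size.
#' @param sizes integer vector of numbers of matched pairs.
#' @param ... forwarded to [run_setting()].
#' @return list with `table` (data.frame: n, power, fdr, power_se, fdr_se)
#'   and `runs` (the underlying `clr_eval` objects, named by size).
#' @export
sample_size_sweep <- function(setting, sizes = c(50, 100, 200, 500), ...) {
  runs <- lapply(sizes, function(n) {
    s <- setting
    s$n_pairs <- n
    run_setting(s, ...)
  })
  names(runs) <- sizes
  tab <- data.frame(
    n = sizes,
    power = vapply(runs, `[[`, numeric(1), "power"),
    fdr = vapply(runs, `[[`, numeric(1), "fdr"),
    power_se = vapply(runs, `[[`, numeric(1), "power_se"),
    fdr_se = vapply(runs, `[[`, numeric(1), "fdr_se"))
  list(table = tab, runs = runs)
}

#' Single-block conditional-lasso baseline
#'
#' Ignores the block structure: all covariates form one block, the penalty
#' level is chosen by cross-validated conditional log-likelihood, and the
#' support of a single fit at that level is returned — no stability
#' selection. This is the single-model baseline that penalized conditional
#' logistic selection is usually compared against.
#'
#' @param d a [matched_data] object.
#' @param alpha elastic-net mixing.
#' @param nfolds CV folds.
#' @param seed seed for the fold shuffle.
#' @param ... passed to [clr_fit()].
#' @return integer vector of selected (nonzero-coefficient) variable indices.
#' @export
single_block_comparator <- function(d, alpha = 1, nfolds = 5, seed = 1, ...) {
  d1 <- d
  d1$block_sizes <- ncol(d$X)
  d1$block <- rep(1L, ncol(d$X))
  d1$block_names <- "all"
  lam <- find_default_lambda(d1, pf = 1, alpha = alpha, nfolds = nfolds,
                             seed = seed, ...)
  which(clr_fit(d1, lambda = lam, alpha = alpha, ...)$nonzero)
}
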