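---
title: "Penalized conditional logistic regression with block-wise penalties: models and methods"
author: "clrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized conditional logistic regression with block-wise penalties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clrnet)
```

## The model

A matched case–control study groups each case with $k \ge 1$ controls matched
on confounders; the matched set is a stratum. Writing $\eta_j = x_j'\beta$ for
the linear predictor of member $j$, the conditional likelihood of stratum $s$
with a single case is

$$
L_s(\beta) \;=\; \frac{\exp(\eta_{\text{case}(s)})}{\sum_{j \in s} \exp(\eta_j)},
$$

so stratum-specific intercepts — and any covariate constant within a stratum —
cancel. The package maximizes $\ell(\beta) = \sum_s \log L_s(\beta)$ minus a
block-structured elastic-net penalty

$$
\operatorname{pen}(\beta) \;=\; \sum_{p=1}^{P} \lambda_p
\Big[\, \alpha \lVert \beta_p \rVert_1 + \tfrac{1-\alpha}{2}
\lVert \beta_p \rVert_2^2 \Big],
$$

where blocks $p = 1, \dots, P$ are contiguous groups of covariate columns
(omics layers), $\lambda_p \ge 0$ is the penalty level of block $p$, and
$\alpha \in (0,1]$ mixes lasso and ridge. Two conventions deserve emphasis:

* **Penalty scale.** Penalties are on the *sum* scale — no $1/n$ factor —
  so the same $\lambda$ penalizes relatively less as strata accrue. $\lambda$
  values are therefore comparable across subsamples of the same study but not
  across studies of different size.
* **Elastic-net mapping.** For block level $\lambda_p$ the $L_1$ part is
  $\alpha\lambda_p$ and the $L_2$ part $(1-\alpha)\lambda_p/2$. Other codes
  parameterize the two penalties independently; any fixed convention gives the
  same method once tuning is done under it, and this one keeps a single
  per-block level with one global mixing knob.

Because the intercepts are conditioned away there is no predicted probability
for a new, unmatched observation; the estimand is the support (and size) of
$\beta$, which is why the package's end point is variable selection.

## The solver

`clr_fit()` minimizes $-\ell(\beta) + \operatorname{pen}(\beta)$ by an
iteratively reweighted least squares (IRLS) outer loop around cyclic
coordinate descent:

1. at the current $\beta$, compute within-stratum softmax weights $w_j$ and
   the diagonal curvature $d_j = w_j(1 - w_j)$, floored at $10^{-5}$ so the
   working response $z_j = \eta_j + (y_j - w_j)/d_j$ stays finite near
   perfectly separated strata;
2. minimize the penalized weighted least-squares surrogate by cyclic
   coordinate descent with soft-thresholding, sweeping all coordinates and
   then iterating over the active set until a full sweep is stable (fixed
   cyclic order = column order, for determinism);
3. recompute the exact penalized objective; if it rose, halve the step toward
   the previous iterate (the surrogate's diagonal curvature is an
   approximation, so monotonicity is enforced rather than assumed).

Soft-thresholding makes zero coefficients *exact* zeros — the nonzero
indicator that stability selection aggregates needs no epsilon. Convergence
is declared when the maximum absolute coefficient change over an outer
iteration falls below `tol` ($10^{-6}$ by default, with at most 100 outer
iterations; non-convergence is flagged in the result, and a flagged fit
counts as selecting nothing inside stability selection). Warm starts along a
decreasing penalty grid (`clr_path()`) make path and cross-validation fits
cheap; a property test confirms warm-started endpoints agree with cold
starts. The all-zero threshold $\lambda_{\max} = \max_j |g_j(0)| /
(\alpha\,pf_{\text{block}(j)})$ comes from the lasso KKT condition at zero
(`clr_lambda_max()`); unpenalized blocks are not supported, since they would
leave $\lambda_{\max}$ undefined.

Columns are *not* standardized by default: user-specified block penalties
refer to the data as given. `standardize = TRUE` scales columns to unit
standard deviation before fitting and reports coefficients on the original
scale.

## Tuning

The penalty vector decomposes as
$\boldsymbol\lambda = \lambda \cdot (1, \lambda_2/\lambda, \dots,
\lambda_P/\lambda)$: an overall level times penalty factors relative to the
first block. The two are tuned separately.

**Penalty factors** (`default_pf()`): fit tentative penalized CLR models —
one per block (`type_step1 = "separate"`) or one joint model (`"joint"`) —
with the overall level chosen by cross-validated conditional log-likelihood,
then set each block's factor inversely proportional to the mean absolute
estimated coefficient of the block, normalized to 1 for the first
non-excluded block. The mean is taken over *all* coefficients of the block,
zeros included: the heuristic targets the block's overall signal density, and
restricting to the nonzero support would reward a block for having few but
inflated survivors. A block whose tentative fit is entirely zero is flagged
for exclusion. Cross-validation makes the result seed-dependent, so
`n_repeats` averages the factors over repeated runs (a block is excluded if
flagged in more than half of them).

**Overall level** (`find_default_lambda()`): a log-spaced grid of 25 values
from $\lambda_{\max}$ down to $0.01\,\lambda_{\max}$ is searched for the
maximum cross-validated conditional log-likelihood, with 5 folds by default
and folds always partitioning strata — a matched set is never split, since
splitting it would change the conditioning set of its likelihood term. The
grid floor of $0.01$ is the usual choice for $p > n$ paths; fits far below it
approach the saturated model (slowly, and without ever winning the
cross-validation) under the strong effect sizes used in the simulation
study. Both the span and the grid size are arguments.

## Stability selection

`stable_clr()` implements the complementary-pairs variant: for each of $B$
random partitions of the $n$ strata, two disjoint half-samples of
$\lfloor n/2 \rfloor$ matched sets are formed (one stratum per partition is
left out when $n$ is odd), giving $2B$ subsamples; $B = 100$ by default.
Each candidate penalty vector is refitted on every subsample, a variable's
selection probability per vector is the fraction of the $2B$ fits with a
nonzero coefficient, and the reported probability is the maximum over
vectors. Probabilities are therefore multiples of $1/(2B)$ and invariant to
the order of the candidate list. Design choices the literature leaves open:

* subsamples are drawn once per call and shared across penalty vectors, so
  comparisons between vectors are not confounded with subsampling noise;
* the threshold comparison is inclusive ($\ge$), so a variable sitting
  exactly at the threshold is selected;
* subsamples are generated before any parallel dispatch, making parallel and
  serial runs identical under the same seed (fits themselves are
  deterministic).

Thresholds in $0.55$–$0.9$ are conventional; `select_variables()` applies
one, and nested selections across thresholds come for free.

## The simulator and what it does (not) emulate

`simulate_matched_data()` draws, for each stratum, $k + 1$ covariate vectors
from a multivariate normal with unit variances, optional exchangeable
within-block correlation $\rho$ (blocks independent), and assigns the case
label to member $j$ with probability $\exp(x_j'\beta) / \sum_l \exp(x_l'\beta)$
— exactly the conditional-logistic mechanism the fitting functions assume,
which makes parameter recovery a well-posed oracle. Matched confounders act
as stratum effects and cancel from this probability, so they need not be
generated. Active variables sit at the head of each block; by exchangeability
of the generator their position is immaterial.

The six benchmark settings (`benchmark_settings()`) share 2 blocks, 100
covariates, 20 active variables and 200 matched pairs, and differ in the
split of dimension ($p_1, p_2$), actives ($a_1, a_2$) and effect size
($\beta_1, \beta_2$) between blocks. The covariate law behind the published
benchmark is not fully specified — the distribution, correlation structure
and scaling of the $\beta_i = 4$ effects are a reconstruction gap — so the
defaults here (standard normal, $\rho = 0$) are one reasonable member of the
compatible family, chosen once. Reference power/FDR values are treated as
stochastic targets with tolerance, not exact truths: a passing harness shows
the pipeline reproduces the *profile* (which settings are easy, how power
scales with $n$, how the threshold trades power against FDR), not that the
generative law is identical. Real omics layers — heavy tails, strong
correlation blocks, batch structure, measurement error — are outside what
these tests exercise.

## The study harness

`run_setting()` runs the full pipeline per simulated dataset: data-adaptive
penalty factors (`separate` tentative models), cross-validated overall level,
then stability selection *with the tuned penalty vector* ($B = 50$ in the
benchmark configuration), and selection at threshold 0.55. Power is the
average fraction of active variables selected; FDR the average fraction of
inactive among selected, a dataset with no selections contributing 0 (the
convention matters and is asserted in tests). Excluded blocks are dropped
before tuning and stability selection; their variables get selection
probability 0. The candidate list is deliberately the single tuned vector —
that is the benchmark procedure — but `lambda_factors` widens it to scaled
multiples, e.g. `c(0.5, 1, 2)`, for the exploratory practice of also trying
penalties away from the data-adaptive point (max-aggregation means added
vectors can only raise selection probabilities, raising power and FDR
together). `threshold_sweep()` re-thresholds stored probabilities without
refitting; `sample_size_sweep()` repeats the pipeline across $n$;
`single_block_comparator()` is the one-fit, one-block baseline whose FDR the
stability pipeline is designed to beat.

## Monte-Carlo scales

Simulation checks in the test suite run at reduced scale, chosen once as a
compromise between Monte-Carlo error and a test suite that stays pleasant to
run: 10–15 datasets per setting with $B = 50$ for the power/FDR profile
(reference values asserted within $\pm 0.10$ absolute, qualitative orderings
strictly), 10 seeds with $B = 15$ for the active/inactive ranking check, and
10 datasets per size for the sample-size sweep at $n \in \{50, 100, 200\}$.
The acceptance script uses 12 datasets at $n = 500$ with $B = 50$. At these
scales the Monte-Carlo standard error of a power or FDR estimate is roughly
0.02–0.05, well inside the asserted tolerances; all runs are fully seeded and
bit-reproducible.

## Known limitations

* 1 case per stratum only (1:k matching); multiple cases per set would need
  the exact conditional likelihood with its combinatorial denominator.
* No unpenalized ("always in") covariates, no group/fused penalties, no
  overlapping blocks.
* Penalty factors from `default_pf()` inherit cross-validation variance;
  averaging repeats helps but the heuristic remains a heuristic — it finds a
  good relative scaling, not an optimum.
* Stability selection here stabilizes the selected set; it does not calibrate
  the threshold for formal error control.
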