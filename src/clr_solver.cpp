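#include <Rcpp.h>
using namespace Rcpp;

// Matched-set layout: observations are pre-sorted by stratum; `starts` gives
// the 0-based offset of each stratum plus a trailing n_obs sentinel. Each
// stratum holds exactly one case (y == 1) and >= 1 controls.

// Conditional log-likelihood for a given linear predictor.
// ll = sum_s [ eta_case(s) - log sum_{j in s} exp(eta_j) ], overflow-safe.
static double loglik_eta(const NumericVector& eta, const IntegerVector& y,
                         const IntegerVector& starts) {
  const int S = starts.size() - 1;
  double ll = 0.0;
  for (int s = 0; s < S; ++s) {
    double m = R_NegInf, eta_case = 0.0;
    for (int i = starts[s]; i < starts[s + 1]; ++i) {
      if (eta[i] > m) m = eta[i];
      if (y[i] == 1) eta_case = eta[i];
    }
    double denom = 0.0;
    for (int i = starts[s]; i < starts[s + 1]; ++i) denom += std::exp(eta[i] - m);
    ll += eta_case - m - std::log(denom);
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_clr_loglik(const NumericMatrix& X, const NumericVector& beta,
                      const IntegerVector& y, const IntegerVector& starts) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector eta(n);
  for (int j = 0; j < p; ++j) {
    const double b = beta[j];
    if (b == 0.0) continue;
    for (int i = 0; i < n; ++i) eta[i] += X(i, j) * b;
  }
  return loglik_eta(eta, y, starts);
}

// Within-stratum softmax weights for a linear predictor.
static void softmax_weights(const NumericVector& eta, const IntegerVector& starts,
                            NumericVector& w) {
  const int S = starts.size() - 1;
  for (int s = 0; s < S; ++s) {
    double m = R_NegInf;
    for (int i = starts[s]; i < starts[s + 1]; ++i)
      if (eta[i] > m) m = eta[i];
    double denom = 0.0;
    for (int i = starts[s]; i < starts[s + 1]; ++i) {
      w[i] = std::exp(eta[i] - m);
      denom += w[i];
    }
    for (int i = starts[s]; i < starts[s + 1]; ++i) w[i] /= denom;
  }
}

// [[Rcpp::export]]
NumericVector cpp_clr_grad(const NumericMatrix& X, const NumericVector& beta,
                           const IntegerVector& y, const IntegerVector& starts) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector eta(n), w(n), g(p);
  for (int j = 0; j < p; ++j) {
    const double b = beta[j];
    if (b == 0.0) continue;
    for (int i = 0; i < n; ++i) eta[i] += X(i, j) * b;
  }
  softmax_weights(eta, starts, w);
  for (int j = 0; j < p; ++j) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += X(i, j) * (y[i] - w[i]);
    g[j] = acc;
  }
  return g;
}

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

static double penalty_value(const NumericVector& beta, const NumericVector& l1,
                            const NumericVector& l2) {
  double pen = 0.0;
  for (int j = 0; j < beta.size(); ++j)
    pen += l1[j] * std::fabs(beta[j]) + 0.5 * l2[j] * beta[j] * beta[j];
  return pen;
}

// One coordinate-descent sweep over the coordinates listed in `idx`.
// r holds the working residual z - eta; den[j] = sum_i d_i x_ij^2.
static double cd_sweep(const NumericMatrix& X, const NumericVector& d,
                       const NumericVector& den, const NumericVector& l1,
                       const NumericVector& l2, NumericVector& beta,
                       NumericVector& r, const std::vector<int>& idx) {
  const int n = X.nrow();
  double max_delta = 0.0;
  for (size_t k = 0; k < idx.size(); ++k) {
    const int j = idx[k];
    const double bj = beta[j];
    double dot = 0.0;
    for (int i = 0; i < n; ++i) dot += d[i] * X(i, j) * r[i];
    const double num = dot + den[j] * bj;
    const double bnew = soft(num, l1[j]) / (den[j] + l2[j]);
    const double delta = bnew - bj;
    if (delta != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= X(i, j) * delta;
      beta[j] = bnew;
      if (std::fabs(delta) > max_delta) max_delta = std::fabs(delta);
    }
  }
  return max_delta;
}

// Penalized fit: minimize -loglik(beta) + sum_j [ l1_j |beta_j| + l2_j/2 beta_j^2 ].
// Outer IRLS loop: quadratic approximation with the diagonal curvature of the
// stratum softmax; inner cyclic coordinate descent with soft-thresholding,
// cycling over the active set between full sweeps (glmnet-style). A
// step-halving safeguard keeps the penalized objective non-increasing.
// [[Rcpp::export]]
List cpp_clr_fit(const NumericMatrix& X, const IntegerVector& y,
                 const IntegerVector& starts, const NumericVector& l1,
                 const NumericVector& l2, NumericVector beta0,
                 double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector beta = clone(beta0);
  NumericVector eta(n), w(n), d(n), den(p), r(n);

  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < p; ++j)
      if (beta[j] != 0.0) acc += X(i, j) * beta[j];
    eta[i] = acc;
  }
  double obj = -loglik_eta(eta, y, starts) + penalty_value(beta, l1, l2);

  bool converged = false;
  int iter = 0;
  const double wmin = 1e-5;
  std::vector<int> all_idx(p), act_idx;
  for (int j = 0; j < p; ++j) all_idx[j] = j;

  for (iter = 1; iter <= max_iter; ++iter) {
    softmax_weights(eta, starts, w);
    // working residual r_i = (y_i - w_i)/d_i, d_i = w_i (1 - w_i)
    for (int i = 0; i < n; ++i) {
      double di = w[i] * (1.0 - w[i]);
      if (di < wmin) di = wmin;
      d[i] = di;
      r[i] = (y[i] - w[i]) / di;
    }
    for (int j = 0; j < p; ++j) {
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += d[i] * X(i, j) * X(i, j);
      den[j] = acc;
    }
    NumericVector beta_old = clone(beta);
    NumericVector eta_old = clone(eta);

    // full sweep, then iterate on the active set, until a full sweep is stable
    const double inner_tol = 0.1 * tol;
    for (int round = 0; round < 20; ++round) {
      double md = cd_sweep(X, d, den, l1, l2, beta, r, all_idx);
      if (md < inner_tol) break;
      act_idx.clear();
      for (int j = 0; j < p; ++j)
        if (beta[j] != 0.0) act_idx.push_back(j);
      for (int inner = 0; inner < 100; ++inner) {
        if (cd_sweep(X, d, den, l1, l2, beta, r, act_idx) < inner_tol) break;
      }
    }

    // eta = eta_old + (z - eta_old) - r, and z - eta_old was the initial r
    for (int i = 0; i < n; ++i)
      eta[i] = eta_old[i] + (y[i] - w[i]) / d[i] - r[i];

    // objective safeguard: halve the step while the penalized objective rises
    for (int h = 0; h <= 30; ++h) {
      double obj_new = -loglik_eta(eta, y, starts) + penalty_value(beta, l1, l2);
      if (obj_new <= obj + 1e-10) {
        obj = obj_new;
        break;
      }
      if (h == 30) {
        beta = clone(beta_old);
        eta = clone(eta_old);
        break;
      }
      for (int j = 0; j < p; ++j) beta[j] = 0.5 * (beta[j] + beta_old[j]);
      for (int i = 0; i < n; ++i) eta[i] = 0.5 * (eta[i] + eta_old[i]);
    }

    double max_change = 0.0;
    for (int j = 0; j < p; ++j) {
      double c = std::fabs(beta[j] - beta_old[j]);
      if (c > max_change) max_change = c;
    }
    if (max_change < tol) {
      converged = true;
      break;
    }
  }

  return List::create(_["beta"] = beta, _["objective"] = obj,
                      _["n_iterations"] = std::min(iter, max_iter),
                      _["converged"] = converged);
}
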