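// Penalised-IRLS bootstrap refits for the standardised-effect estimator.
// Mirrors the R reference implementation (ridge_irls): Newton steps with
// step-halving on the penalised binomial log-likelihood.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double log1pexp_scalar(double x) {
  if (x > 35.0) return x;
  return std::log1p(std::exp(x));
}

static double pen_loglik(const vec& y, const vec& eta, const vec& d,
                         const vec& beta) {
  double ll = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) {
    ll += y[i] * eta[i] - log1pexp_scalar(eta[i]);
  }
  return ll - dot(d, beta % beta);
}

// one penalised IRLS solve; returns true on convergence
static bool irls_fit(const mat& X, const vec& y, const vec& d, vec& beta,
                     int max_iter, double tol) {
  const double n = static_cast<double>(y.n_elem);
  vec eta = X * beta;
  double f = pen_loglik(y, eta, d, beta);
  for (int it = 0; it < max_iter; ++it) {
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = clamp(mu % (1.0 - mu), 1e-10, datum::inf);
    vec grad = X.t() * (y - mu) - 2.0 * (d % beta);
    mat H = X.t() * (X.each_col() % w);
    H.diag() += 2.0 * d;
    vec step;
    if (!solve(step, H, grad, solve_opts::likely_sympd + solve_opts::no_approx)) {
      return false;
    }
    double alpha = 1.0;
    vec beta_new, eta_new;
    double f_new = f;
    while (true) {
      beta_new = beta + alpha * step;
      eta_new = X * beta_new;
      f_new = pen_loglik(y, eta_new, d, beta_new);
      if (std::isfinite(f_new) && f_new >= f - 1e-12) break;
      alpha /= 2.0;
      if (alpha < 1e-10) break;
    }
    double moved = max(abs(beta_new - beta));
    beta = beta_new;
    eta = eta_new;
    double improved = f_new - f;
    f = f_new;
    if (moved < tol || (it > 0 && improved < 1e-12 &&
                        max(abs(grad)) < 1e-6 * std::max(1.0, n))) {
      vec mu2 = 1.0 / (1.0 + exp(-eta));
      vec grad2 = X.t() * (y - mu2) - 2.0 * (d % beta);
      return max(abs(grad2)) < 1e-5 * std::max(1.0, n);
    }
  }
  return false;
}

// Refit + restandardise over a matrix of bootstrap index columns.
// X: standardised design incl. intercept column; tcol (0-based): the
// treatment column; v1/v0: its counterfactual values on that scale.
// Returns one row per replicate: (log RR, log OR, RD); NaN row = failure.
// [[Rcpp::export]]
arma::mat boot_replicates_cpp(const arma::mat& X, const arma::vec& y,
                              const arma::vec& d, const arma::vec& beta_init,
                              const arma::umat& idx, const int tcol,
                              const double v1, const double v0,
                              const int max_iter, const double tol) {
  const uword n_reps = idx.n_cols;
  mat out(n_reps, 3);
  out.fill(datum::nan);
  for (uword r = 0; r < n_reps; ++r) {
    uvec rows = idx.col(r);
    vec yb = y.elem(rows);
    if (all(yb == yb[0])) continue;            // single-class resample
    mat Xb = X.rows(rows);
    vec beta = beta_init;
    bool ok = irls_fit(Xb, yb, d, beta, max_iter, tol);
    if (!ok && accu(d) > 0.0) continue;        // penalised fit must converge
    vec base = Xb * beta;
    vec tvals = Xb.col(tcol);
    vec eta1 = base + (v1 - tvals) * beta[tcol];
    vec eta0 = base + (v0 - tvals) * beta[tcol];
    double p1 = mean(1.0 / (1.0 + exp(-eta1)));
    double p0 = mean(1.0 / (1.0 + exp(-eta0)));
    if (p1 <= 0.0 || p1 >= 1.0 || p0 <= 0.0 || p0 >= 1.0) continue;
    out(r, 0) = std::log(p1 / p0);
    out(r, 1) = std::log(p1 / (1.0 - p1)) - std::log(p0 / (1.0 - p0));
    out(r, 2) = p1 - p0;
  }
  return out;
}
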