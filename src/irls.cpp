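// Iteratively reweighted least squares with a Tukey bisquare weight
// function, plus a bulk driver for pairs bootstrap across regions sharing
// one resampled year sequence per iteration.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double mad_scale(const arma::vec& r) {
  // median(|r|) / 0.6745, the usual robust scale for M-estimation
  return arma::median(arma::abs(r)) / 0.6745;
}

static bool irls_core(const arma::mat& X, const arma::vec& y, double c,
                      int maxit, double tol, arma::vec& beta, int& iters) {
  arma::vec beta_new;
  // OLS start
  if (!arma::solve(beta, X.t() * X, X.t() * y, arma::solve_opts::no_approx))
    return false;
  iters = 0;
  double s = 0.0;
  for (int it = 0; it < maxit; ++it) {
    arma::vec r = y - X * beta;
    // re-estimate the robust scale early on, then freeze it: the discrete
    // jumps of the MAD can otherwise lock the iteration into a two-cycle
    if (it < 50) s = mad_scale(r);
    if (s < 1e-12) { iters = it; return true; } // (near-)exact fit
    arma::vec u = r / (c * s);
    arma::vec w = arma::square(1.0 - arma::square(u));
    w.elem(arma::find(arma::abs(u) >= 1.0)).zeros();
    if (arma::accu(w) < 1e-10) { iters = it; return true; }
    arma::mat Xw = X.each_col() % w;
    if (!arma::solve(beta_new, Xw.t() * X, Xw.t() * y, arma::solve_opts::no_approx))
      return false;
    double delta = arma::abs(beta_new - beta).max();
    beta = beta_new;
    iters = it + 1;
    if (delta < tol) return true;
  }
  return false;
}

// [[Rcpp::export]]
List cpp_irls_bisquare(const arma::mat& X, const arma::vec& y,
                       double c = 4.685, int maxit = 300, double tol = 1e-8) {
  arma::vec beta;
  int iters = 0;
  bool conv = irls_core(X, y, c, maxit, tol, beta, iters);
  arma::vec resid = y - X * beta;
  return List::create(_["coef"] = beta, _["residuals"] = resid,
                      _["iterations"] = iters, _["converged"] = conv);
}

// Y, S: n x R matrices of log burned area and SPEI (columns = regions).
// trend: n-vector of the (centred) trend covariate.
// use_trend: length-R logical.
// idx: n x B matrix of 1-based resampled year indices shared across regions.
// Returns a B x 3 x R array of (beta1, beta2, beta3) replicates.
// [[Rcpp::export]]
arma::cube cpp_bootstrap_irls(const arma::mat& Y, const arma::mat& S,
                              const arma::vec& trend,
                              const LogicalVector& use_trend,
                              const arma::umat& idx,
                              double c = 4.685, int maxit = 300,
                              double tol = 1e-8) {
  const arma::uword n = Y.n_rows, R = Y.n_cols, B = idx.n_cols;
  arma::cube out(B, 3, R, arma::fill::value(NA_REAL));
  for (arma::uword b = 0; b < B; ++b) {
    arma::uvec rows = idx.col(b) - 1;
    arma::vec tr = trend.elem(rows);
    for (arma::uword r = 0; r < R; ++r) {
      arma::vec y = Y.col(r); y = y.elem(rows);
      arma::vec s = S.col(r); s = s.elem(rows);
      bool wt = use_trend[r];
      arma::mat X(n, wt ? 3 : 2);
      X.col(0).ones();
      X.col(1) = s;
      if (wt) X.col(2) = tr;
      arma::vec beta; int iters = 0;
      if (irls_core(X, y, c, maxit, tol, beta, iters)) {
        out(b, 0, r) = beta(0);
        out(b, 1, r) = beta(1);
        out(b, 2, r) = wt ? beta(2) : 0.0;
      }
    }
  }
  return out;
}

// Exceedance counts for the shared-sequence permutation test: for each
// permutation (column of perms, 1-based), the year-shuffled correlations of
// every region are compared against the observed ones (lower tail).
// Xs, Ys: n x R standardized matrices.
// [[Rcpp::export]]
arma::vec cpp_perm_exceed(const arma::mat& Xs, const arma::mat& Ys,
                          const arma::umat& perms, const arma::vec& r_obs) {
  const arma::uword n = Xs.n_rows, R = Xs.n_cols, B = perms.n_cols;
  arma::vec exceed(R, arma::fill::zeros);
  for (arma::uword b = 0; b < B; ++b) {
    arma::uvec rows = perms.col(b) - 1;
    arma::mat Xp = Xs.rows(rows);
    arma::rowvec r = arma::sum(Xp % Ys, 0) / (n - 1);
    for (arma::uword j = 0; j < R; ++j)
      if (r(j) <= r_obs(j)) exceed(j) += 1.0;
  }
  return exceed;
}
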