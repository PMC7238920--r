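// Permutation-subsampled Mahalanobis / |Z| scoring core.
// All randomness lives in R (the index matrix is drawn there); this routine
// is purely deterministic numerics so the R and compiled paths agree exactly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// X: pool (n x p) of control residuals; s: subject profile (p);
// idx: n_perm x subset_size of 1-based row indices into X;
// shrink: 1 = diagonal-target shrinkage covariance, 0 = sample covariance;
// sd_fixed: length-p SDs to use for |Z| (empty -> per-subsample SD).
// [[Rcpp::export]]
Rcpp::List perm_scores_cpp(const arma::mat& X, const arma::vec& s,
                           const arma::imat& idx, const int shrink,
                           const arma::vec& sd_fixed) {
  const uword n_perm = idx.n_rows;
  const uword m = idx.n_cols;
  const uword p = X.n_cols;
  if (s.n_elem != p) Rcpp::stop("profile length does not match pool");

  vec mvals(n_perm);
  mat zvals(n_perm, p);
  mat sub(m, p);

  for (uword r = 0; r < n_perm; ++r) {
    for (uword j = 0; j < m; ++j) sub.row(j) = X.row(idx(r, j) - 1);
    rowvec mu = mean(sub, 0);
    mat Xc = sub.each_row() - mu;
    mat cp = Xc.t() * Xc;
    mat S = cp / double(m - 1);
    mat C = S;
    if (shrink) {
      // lambda = sum_offdiag Var^(S_ij) / sum_offdiag S_ij^2, clipped to [0,1]
      mat Xc2 = Xc % Xc;
      mat W2 = Xc2.t() * Xc2;
      mat wbar = cp / double(m);
      mat varS = double(m) / std::pow(double(m - 1), 3) *
                 (W2 - double(m) * (wbar % wbar));
      double num = accu(varS) - trace(varS);
      double den = accu(S % S) - accu(square(S.diag()));
      double lambda = (den <= 0.0) ? 1.0
                      : std::min(1.0, std::max(num / den, 0.0));
      lambda = std::max(lambda, 1e-12);
      C = (1.0 - lambda) * S;
      C.diag() = S.diag();
    }
    mat R;
    if (!chol(R, C))
      Rcpp::stop("covariance not positive definite in permutation %d", r + 1);
    vec d = s - mu.t();
    vec u = solve(trimatl(R.t()), d);
    mvals(r) = std::sqrt(dot(u, u));
    if (sd_fixed.n_elem == p)
      zvals.row(r) = (abs(d) / sd_fixed).t();
    else
      zvals.row(r) = (abs(d) / sqrt(S.diag())).t();
  }
  return Rcpp::List::create(Rcpp::Named("m") = mvals,
                            Rcpp::Named("z") = zvals);
}
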