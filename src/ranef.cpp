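// Conjugate draw of the per-subject random-effect vectors in the
// hierarchical robust regression.
//
// For subject s the full conditional of u_s (length d = 2R: intercept and
// session slope per response) is Normal with precision
//   P_s = SigmaInv + blockdiag_j( [a11 a12; a12 a22]_{s,j} )
// and linear term b_s (stacked per response). The sufficient statistics
// a*, b* are accumulated in R (weighted by the Student-t scale-mixture
// weights and residual variances); the standard-normal innovations z are
// drawn in R so the whole sampler consumes one RNG stream.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::mat sample_ranef_cpp(const arma::mat& SigmaInv,
                           const arma::mat& a11, const arma::mat& a12,
                           const arma::mat& a22, const arma::mat& b1,
                           const arma::mat& b2, const arma::mat& z) {
  const int S = a11.n_rows;
  const int R = a11.n_cols;
  const int d = 2 * R;
  arma::mat U(S, d);
  arma::mat P(d, d);
  arma::vec rhs(d), mu(d), u(d);

  for (int s = 0; s < S; ++s) {
    P = SigmaInv;
    for (int j = 0; j < R; ++j) {
      P(2 * j, 2 * j)         += a11(s, j);
      P(2 * j, 2 * j + 1)     += a12(s, j);
      P(2 * j + 1, 2 * j)     += a12(s, j);
      P(2 * j + 1, 2 * j + 1) += a22(s, j);
      rhs(2 * j) = b1(s, j);
      rhs(2 * j + 1) = b2(s, j);
    }
    arma::mat L = arma::chol(P, "lower");
    mu = arma::solve(arma::trimatu(L.t()),
                     arma::solve(arma::trimatl(L), rhs));
    u = mu + arma::solve(arma::trimatu(L.t()), z.col(s));
    U.row(s) = u.t();
  }
  return U;
}
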