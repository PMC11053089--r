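// Coordinate-descent core of the graphical lasso.
//
// Block-coordinate algorithm on the working covariance W: each column j is
// updated by solving a lasso subproblem 0.5 b'W11 b - s12'b + lambda|b|_1
// by cyclic coordinate descent. The diagonal is unpenalized (w_jj = s_jj).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export]]
Rcpp::List glasso_fit_cpp(const arma::mat& S, double lambda,
                          arma::mat B, arma::mat W,
                          double tol, int max_sweep) {
  const int p = S.n_cols;
  W.diag() = S.diag();
  double offmean = 0.0;
  int cnt = 0;
  for (int a = 0; a < p; ++a)
    for (int b = a + 1; b < p; ++b) { offmean += std::fabs(S(a, b)); ++cnt; }
  const double thr = tol * (cnt ? offmean / cnt : 1.0) + 1e-12;

  arma::vec beta(p - 1), s12(p - 1);
  arma::mat W11(p - 1, p - 1);
  arma::uvec idx(p - 1);

  for (int sweep = 0; sweep < max_sweep; ++sweep) {
    double max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      int c = 0;
      for (int k = 0; k < p; ++k) if (k != j) idx(c++) = k;
      W11 = W.submat(idx, idx);
      for (int k = 0; k < p - 1; ++k) s12(k) = S(idx(k), j);
      beta = B.col(j);
      for (int it = 0; it < 200; ++it) {
        double db = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double r = s12(k) - arma::dot(W11.row(k), beta) +
                     W11(k, k) * beta(k);
          double bnew = soft(r, lambda) / W11(k, k);
          db = std::max(db, std::fabs(bnew - beta(k)));
          beta(k) = bnew;
        }
        if (db < thr) break;
      }
      B.col(j) = beta;
      arma::vec w12 = W11 * beta;
      for (int k = 0; k < p - 1; ++k) {
        max_delta = std::max(max_delta, std::fabs(W(idx(k), j) - w12(k)));
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    if (max_delta < thr) break;
  }

  arma::mat Theta(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    int c = 0;
    double dot = 0.0;
    for (int k = 0; k < p; ++k) if (k != j) { dot += W(k, j) * B(c, j); ++c; }
    double tjj = 1.0 / (W(j, j) - dot);
    Theta(j, j) = tjj;
    c = 0;
    for (int k = 0; k < p; ++k) if (k != j) { Theta(k, j) = -B(c, j) * tjj; ++c; }
  }
  Theta = (Theta + Theta.t()) / 2.0;
  Theta.clean(1e-12);

  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("B") = B,
                            Rcpp::Named("Theta") = Theta);
}
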