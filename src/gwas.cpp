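#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Per-variant logistic regression y ~ [X | g_j] by Newton-Raphson
// (iteratively reweighted least squares), convergence when the largest
// coefficient change drops below `tol`, capped at `max_iter` iterations.
// Warm-started from the covariate-only fit.  Returns an m x 3 matrix:
// per-variant Wald beta, se, and a converged flag (0 also marks
// separation / singular information).
// [[Rcpp::export]]
arma::mat cpp_logistic_gwas(const arma::mat& X, const arma::mat& G,
                            const arma::vec& y, double tol, int max_iter) {
  const uword n = X.n_rows, c = X.n_cols, m = G.n_cols;
  mat out(m, 3, fill::zeros);

  // covariate-only fit for the warm start
  vec b0(c, fill::zeros);
  for (int it = 0; it < max_iter; ++it) {
    vec eta = X * b0;
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
    mat H = X.t() * (X.each_col() % w);
    vec g = X.t() * (y - mu);
    vec d;
    if (!solve(d, H, g, solve_opts::likely_sympd + solve_opts::no_approx)) break;
    b0 += d;
    if (abs(d).max() < tol) break;
  }

  mat D(n, c + 1);
  D.cols(0, c - 1) = X;
  for (uword j = 0; j < m; ++j) {
    D.col(c) = G.col(j);
    vec b(c + 1, fill::zeros);
    b.head(c) = b0;
    bool conv = false, ok = true;
    mat H;
    for (int it = 0; it < max_iter; ++it) {
      vec eta = D * b;
      vec mu = 1.0 / (1.0 + exp(-eta));
      vec w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
      H = D.t() * (D.each_col() % w);
      vec g = D.t() * (y - mu);
      vec d;
      if (!solve(d, H, g, solve_opts::likely_sympd + solve_opts::no_approx)) {
        ok = false; break;
      }
      b += d;
      if (abs(d).max() < tol) { conv = true; break; }
      if (std::abs(b(c)) > 50.0) { ok = false; break; }  // separation guard
    }
    double beta = b(c), se = datum::nan;
    if (ok) {
      mat Hi;
      if (inv_sympd(Hi, H)) se = std::sqrt(Hi(c, c)); else ok = false;
    }
    out(j, 0) = beta;
    out(j, 1) = se;
    out(j, 2) = (conv && ok && std::isfinite(se)) ? 1.0 : 0.0;
  }
  return out;
}
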