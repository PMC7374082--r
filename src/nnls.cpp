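// Lawson-Hanson active-set non-negative least squares, applied
// column-wise over a matrix of pixel spectra. Solves exactly
//   min ||E c - a||_2  s.t.  c >= 0
// per pixel; the active-set iteration terminates at the KKT point, so on
// pixels with a strictly positive solution it agrees with unconstrained
// least squares.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec nnls_one(const mat& E, const vec& a, double tol, int maxit) {
  const uword k = E.n_cols;
  std::vector<bool> passive(k, false);
  vec x(k, fill::zeros);
  vec w = E.t() * a;  // gradient of -0.5*||Ea - c||^2 at x = 0
  int iter = 0;

  while (true) {
    // pick the inactive coordinate with the most positive gradient
    double wmax = tol;
    sword t = -1;
    for (uword j = 0; j < k; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = j; }
    }
    if (t < 0) break;  // KKT satisfied
    passive[t] = true;

    while (true) {
      if (++iter > maxit) Rcpp::stop("NNLS failed to converge");
      uvec idx(k);
      uword np = 0;
      for (uword j = 0; j < k; ++j) if (passive[j]) idx(np++) = j;
      idx = idx.head(np);
      vec z = solve(E.cols(idx), a);
      if (z.min() > 0) {
        x.zeros();
        x(idx) = z;
        break;
      }
      // step toward z until the first passive coordinate hits zero
      double alpha = datum::inf;
      for (uword i = 0; i < np; ++i) {
        if (z(i) <= 0) {
          double xi = x(idx(i));
          double aq = xi / (xi - z(i));
          if (aq < alpha) alpha = aq;
        }
      }
      for (uword i = 0; i < np; ++i)
        x(idx(i)) += alpha * (z(i) - x(idx(i)));
      for (uword j = 0; j < k; ++j) {
        if (passive[j] && x(j) <= tol) { passive[j] = false; x(j) = 0; }
      }
    }
    w = E.t() * (a - E * x);
  }
  return x;
}

// E: C x K basis; A: C x N pixel absorbances (one column per pixel).
// Returns K x N non-negative concentrations.
// [[Rcpp::export]]
arma::mat nnls_cols(const arma::mat& E, const arma::mat& A) {
  const uword n = A.n_cols;
  mat out(E.n_cols, n);
  const double scale = std::max(1.0, arma::abs(A).max());
  const double tol = 1e-12 * scale * std::max(1.0, arma::abs(E).max());
  const int maxit = 30 * static_cast<int>(E.n_cols) + 50;
  for (uword j = 0; j < n; ++j)
    out.col(j) = nnls_one(E, A.col(j), tol, maxit);
  return out;
}
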