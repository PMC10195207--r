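#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set solver for min ||A x - b||_2 subject to x >= 0.
// Columns enter the passive set one at a time on the most positive gradient
// of the dual; inner loop backtracks when an unconstrained passive solve
// turns a coefficient negative.
// [[Rcpp::export]]
Rcpp::List nnls_cpp(const arma::mat& A, const arma::vec& b,
                    double tol = -1.0, int max_iter = 0) {
  const uword n = A.n_cols;
  if (max_iter <= 0) max_iter = 3 * static_cast<int>(n) + 30;
  if (tol <= 0) tol = 10.0 * datum::eps * norm(A, "inf") * static_cast<double>(A.n_rows);

  vec x(n, fill::zeros);
  std::vector<bool> passive(n, false);
  vec w = A.t() * b;        // gradient at x = 0
  int outer = 0;

  while (outer < max_iter) {
    // most violated dual among active constraints
    double wmax = -datum::inf;
    sword t = -1;
    for (uword j = 0; j < n; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = static_cast<sword>(j); }
    }
    if (t < 0 || wmax <= tol) break;
    passive[static_cast<uword>(t)] = true;
    ++outer;

    int inner = 0;
    while (inner++ < max_iter) {
      uvec pidx(n);
      uword np = 0;
      for (uword j = 0; j < n; ++j) if (passive[j]) pidx(np++) = j;
      pidx.resize(np);

      vec zp;
      const bool ok = solve(zp, A.cols(pidx), b);
      if (!ok) { passive[static_cast<uword>(t)] = false; break; }

      if (zp.min() > 0.0) {
        x.zeros();
        x(pidx) = zp;
        break;
      }
      // step from x toward z until the first passive coefficient hits zero
      double alpha = datum::inf;
      for (uword k = 0; k < np; ++k) {
        const uword j = pidx(k);
        if (zp(k) <= 0.0) {
          const double denom = x(j) - zp(k);
          if (denom > 0.0) {
            const double a = x(j) / denom;
            if (a < alpha) alpha = a;
          }
        }
      }
      if (!std::isfinite(alpha)) alpha = 0.0;
      vec z(n, fill::zeros);
      z(pidx) = zp;
      x += alpha * (z - x);
      for (uword j = 0; j < n; ++j) {
        if (passive[j] && x(j) <= tol) { passive[j] = false; x(j) = 0.0; }
      }
    }
    w = A.t() * (b - A * x);
  }

  const vec r = b - A * x;
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("rnorm") = norm(r, 2),
                            Rcpp::Named("iterations") = outer);
}
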