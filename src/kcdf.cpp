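#include <Rcpp.h>
using namespace Rcpp;

// Kernel estimates of each gene's cumulative density, evaluated at the
// gene's own observed values. Both kernels are O(p * n^2); this is the hot
// loop of the scoring pipeline, hence compiled.

// Gaussian kernel: z_ij = (1/n) sum_k Phi((x_ij - x_ik) / h_i)
// [[Rcpp::export]]
NumericMatrix cpp_kcdf_gaussian(NumericMatrix x, NumericVector h) {
  const int p = x.nrow(), n = x.ncol();
  NumericMatrix z(p, n);
  for (int i = 0; i < p; ++i) {
    const double hi = h[i];
    for (int j = 0; j < n; ++j) {
      const double xij = x(i, j);
      double acc = 0.0;
      for (int k = 0; k < n; ++k)
        acc += R::pnorm((xij - x(i, k)) / hi, 0.0, 1.0, 1, 0);
      z(i, j) = acc / n;
    }
  }
  return z;
}

// Poisson kernel: z_ij = (1/n) sum_k P(Y <= x_ij), Y ~ Pois(x_ik + r).
// R::ppois accumulates the pmf via the regularized incomplete gamma
// function, which is numerically stable for large means.
// [[Rcpp::export]]
NumericMatrix cpp_kcdf_poisson(NumericMatrix x, double offset) {
  const int p = x.nrow(), n = x.ncol();
  NumericMatrix z(p, n);
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < n; ++j) {
      const double xij = x(i, j);
      double acc = 0.0;
      for (int k = 0; k < n; ++k)
        acc += R::ppois(xij, x(i, k) + offset, 1, 0);
      z(i, j) = acc / n;
    }
  }
  return z;
}
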