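#include <Rcpp.h>
using namespace Rcpp;

// Gaussian product-kernel density sum for one class.
// Returns the mean kernel value per query row, i.e. the KDE density
// f(q) = 1/(n (2 pi)^{d/2} h^d) * sum_j exp(-||q - x_j||^2 / (2 h^2)).
// Exponents below -60 are skipped: they contribute < 1e-26 relative mass.
// [[Rcpp::export]]
NumericVector kde_density_cpp(NumericMatrix q, NumericMatrix x, double h) {
  const int m = q.nrow(), n = x.nrow(), d = q.ncol();
  if (x.ncol() != d) stop("dimension mismatch between query and training");
  const double inv2h2 = 1.0 / (2.0 * h * h);
  const double norm =
      std::pow(2.0 * M_PI, -0.5 * d) * std::pow(h, -(double)d) / (double)n;
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      double ss = 0.0;
      for (int k = 0; k < d; ++k) {
        const double t = q(i, k) - x(j, k);
        ss += t * t;
      }
      const double e = ss * inv2h2;
      if (e < 60.0) s += std::exp(-e);
    }
    out[i] = norm * s;
  }
  return out;
}

// Two-class posterior w f1 / (w f1 + (1 - w) f0) per query row.
// The shared kernel normalising constant cancels in the ratio, so only the
// per-class mean kernel sums are needed.  Rows where both sums underflow to
// zero return 0 (no influence far from all training data).
// [[Rcpp::export]]
NumericVector kde_posterior_cpp(NumericMatrix q, NumericMatrix x1,
                                NumericMatrix x0, double w, double h) {
  const int m = q.nrow(), n1 = x1.nrow(), n0 = x0.nrow(), d = q.ncol();
  if (x1.ncol() != d || x0.ncol() != d)
    stop("dimension mismatch between query and training");
  const double inv2h2 = 1.0 / (2.0 * h * h);
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double s1 = 0.0, s0 = 0.0;
    for (int j = 0; j < n1; ++j) {
      double ss = 0.0;
      for (int k = 0; k < d; ++k) {
        const double t = q(i, k) - x1(j, k);
        ss += t * t;
      }
      const double e = ss * inv2h2;
      if (e < 60.0) s1 += std::exp(-e);
    }
    for (int j = 0; j < n0; ++j) {
      double ss = 0.0;
      for (int k = 0; k < d; ++k) {
        const double t = q(i, k) - x0(j, k);
        ss += t * t;
      }
      const double e = ss * inv2h2;
      if (e < 60.0) s0 += std::exp(-e);
    }
    const double f1 = w * s1 / (double)n1;
    const double f0 = (1.0 - w) * s0 / (double)n0;
    const double tot = f1 + f0;
    out[i] = (tot > 0.0) ? f1 / tot : 0.0;
  }
  return out;
}
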