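#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy template counts (Richman & Moorman): B = pairs of
// length-m templates within Chebyshev tolerance r, A = pairs of length
// m+1 templates. Self-matches excluded; i < j pairs counted once.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;          // number of (m+1)-capable templates
  if (nt < 2) return NumericVector::create(0.0, 0.0);
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double diff = std::fabs(x[i + k] - x[j + k]);
        if (diff > d) d = diff;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double diff = std::fabs(x[i + m] - x[j + m]);
      if (diff <= r && d <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
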