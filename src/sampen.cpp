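#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman & Moorman):
// over the N - m templates that admit an (m+1)-length extension,
// B counts pairs whose length-m templates are within Chebyshev
// distance r (self-matches excluded), and A counts the subset whose
// length-(m+1) extensions also match.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int N = n - m;  // templates with an extension
  double A = 0.0, B = 0.0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (ok) {
        B += 1.0;
        if (std::abs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}
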