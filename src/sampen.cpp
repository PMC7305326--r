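#include <Rcpp.h>
using namespace Rcpp;

// Sample-entropy match counts under the Chebyshev (max) distance.
// Templates start at i = 0..n-m-1 so that every counted m-template also has
// an (m+1)-sample extension; self-matches are excluded.  Returns c(B, A):
// B = #pairs matching at length m, A = #pairs matching at length m+1.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double tol) {
  const int n = x.size();
  const int nt = n - m;  // number of templates with an extension
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > tol) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::abs(x[i + m] - x[j + m]) <= tol) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}
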