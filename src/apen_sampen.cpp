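#include <Rcpp.h>
using namespace Rcpp;

// Template-match counting shared by approximate and sample entropy,
// Chebyshev distance, tolerance r.
//
// Returns c(phi_m, phi_{m+1}, A, B) where the phis include self-matches
// (ApEn convention) and A/B count distinct template pairs of length m+1 / m
// over the common n-m template set, self-matches excluded (SampEn).
// [[Rcpp::export(name = ".apen_sampen_counts")]]
NumericVector apen_sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nm = n - m + 1;  // templates of length m
  const int np = n - m;      // templates of length m + 1
  if (np < 1) stop("window too short for the embedding dimension");
  std::vector<double> cm(nm, 1.0), cp(np, 1.0);  // self-matches included
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nm; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      bool okm = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > r) { okm = false; break; }
      }
      if (!okm) continue;
      cm[i] += 1.0;
      cm[j] += 1.0;
      if (i < np && j < np) {
        B += 1.0;
        if (std::abs(x[i + m] - x[j + m]) <= r) {
          A += 1.0;
          cp[i] += 1.0;
          cp[j] += 1.0;
        }
      }
    }
  }
  double phi_m = 0.0, phi_p = 0.0;
  for (int i = 0; i < nm; ++i) phi_m += std::log(cm[i] / nm);
  phi_m /= nm;
  for (int i = 0; i < np; ++i) phi_p += std::log(cp[i] / np);
  phi_p /= np;
  return NumericVector::create(phi_m, phi_p, A, B);
}
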