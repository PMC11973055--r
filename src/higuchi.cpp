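#include <Rcpp.h>
using namespace Rcpp;

// Normalized Higuchi curve lengths L(k), k = 1..kmax.
// [[Rcpp::export(name = ".higuchi_lengths")]]
NumericVector higuchi_lengths(NumericVector x, int kmax) {
  const int n = x.size();
  NumericVector lk(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double lsum = 0.0;
    for (int m = 0; m < k; ++m) {
      const int nseg = (n - 1 - m) / k;
      if (nseg < 1) continue;
      double s = 0.0;
      for (int i = 1; i <= nseg; ++i) {
        s += std::abs(x[m + i * k] - x[m + (i - 1) * k]);
      }
      lsum += s * (n - 1) / (static_cast<double>(nseg) * k) / k;
    }
    lk[k - 1] = lsum / k;
  }
  return lk;
}
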