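#include <Rcpp.h>
using namespace Rcpp;

// mean log fraction of m-length template matches within Chebyshev
// distance r, self-matches included (Pincus phi^m)
// [[Rcpp::export]]
double apen_phi_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int N = n - m + 1;
  if (N <= 0) return NA_REAL;
  double sumlog = 0.0;
  for (int i = 0; i < N; ++i) {
    int count = 0;
    for (int j = 0; j < N; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) break;
      }
      if (d <= r) ++count;
    }
    sumlog += std::log((double)count / (double)N);
  }
  return sumlog / (double)N;
}
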