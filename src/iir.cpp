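#include <Rcpp.h>
using namespace Rcpp;

// direct-form II transposed IIR filter, applied down each column;
// a[0] is assumed normalised to 1
// [[Rcpp::export]]
NumericMatrix iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericMatrix x) {
  const int nb = b.size(), na = a.size();
  const int nstate = std::max(nb, na) - 1;
  const int n = x.nrow(), k = x.ncol();
  NumericMatrix y(n, k);
  std::vector<double> bb(nstate + 1, 0.0), aa(nstate + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nstate);
  for (int c = 0; c < k; ++c) {
    std::fill(z.begin(), z.end(), 0.0);
    for (int t = 0; t < n; ++t) {
      double xt = x(t, c);
      double yt = bb[0] * xt + z[0];
      for (int s = 0; s < nstate - 1; ++s)
        z[s] = bb[s + 1] * xt + z[s + 1] - aa[s + 1] * yt;
      z[nstate - 1] = bb[nstate] * xt - aa[nstate] * yt;
      y(t, c) = yt;
    }
  }
  return y;
}
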