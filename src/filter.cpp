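#include <Rcpp.h>
using namespace Rcpp;

// Same-length FIR filtering along the columns of a matrix (zero-padded ends);
// used to band-limit white noise to the pulse band.
// [[Rcpp::export]]
NumericMatrix fir_filter_cols_cpp(NumericMatrix x, NumericVector h) {
  const int n = x.nrow(), m = x.ncol(), K = h.size();
  const int half = K / 2;
  NumericMatrix out(n, m);
  const double *ph = REAL(h);
  for (int c = 0; c < m; ++c) {
    const double *pc = &x(0, c);
    double *po = &out(0, c);
    for (int r = 0; r < n; ++r) {
      double acc = 0.0;
      const int k0 = std::max(0, half - r);
      const int k1 = std::min(K - 1, n - 1 - r + half);
      for (int k = k0; k <= k1; ++k) acc += ph[k] * pc[r + k - half];
      po[r] = acc;
    }
  }
  return out;
}
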