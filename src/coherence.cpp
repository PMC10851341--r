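#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-pixel normalized spatial coherence at lags 1..M.
//
// For each pixel (n, l) and lag m the value is the average over element pairs
// (i, i+m) of the zero-lag correlation coefficient of the two channels over an
// axial kernel of k samples centered on n (symmetrically truncated at the
// image edges):
//   R(m) = 1/(N-m) * sum_i [ sum_n s_i s_{i+m} / sqrt(sum_n s_i^2 sum_n s_{i+m}^2) ]
// Pairs whose kernel energy vanishes on either channel contribute 0.
// [[Rcpp::export]]
NumericVector coh_stack_cpp(NumericVector cube, int M, int k) {
  IntegerVector dm = cube.attr("dim");
  const int nt = dm[0], N = dm[1], L = dm[2];
  if (M < 1 || M > N - 1) stop("coh_stack_cpp: need 1 <= M <= N-1");
  if (k < 1 || k % 2 == 0) stop("coh_stack_cpp: kernel length must be odd and >= 1");
  const int half = k / 2;
  const double *pc = REAL(cube);
  NumericVector out(static_cast<R_xlen_t>(nt) * L * M);
  double *po = REAL(out);

  std::vector<double> csq(static_cast<size_t>(nt + 1) * N);  // energy cumsums
  std::vector<double> cc(nt + 1);                            // cross cumsum
  std::vector<double> acc(nt);

  for (int l = 0; l < L; ++l) {
    const double *pl = pc + static_cast<R_xlen_t>(l) * nt * N;
    for (int i = 0; i < N; ++i) {
      const double *s = pl + static_cast<R_xlen_t>(i) * nt;
      double *cs = &csq[static_cast<size_t>(i) * (nt + 1)];
      cs[0] = 0.0;
      for (int n = 0; n < nt; ++n) cs[n + 1] = cs[n] + s[n] * s[n];
    }
    for (int m = 1; m <= M; ++m) {
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int i = 0; i + m < N; ++i) {
        const double *si = pl + static_cast<R_xlen_t>(i) * nt;
        const double *sj = pl + static_cast<R_xlen_t>(i + m) * nt;
        const double *ei = &csq[static_cast<size_t>(i) * (nt + 1)];
        const double *ej = &csq[static_cast<size_t>(i + m) * (nt + 1)];
        cc[0] = 0.0;
        for (int n = 0; n < nt; ++n) cc[n + 1] = cc[n] + si[n] * sj[n];
        for (int n = 0; n < nt; ++n) {
          const int lo = std::max(0, n - half);
          const int hi = std::min(nt - 1, n + half);
          const double den2 = (ei[hi + 1] - ei[lo]) * (ej[hi + 1] - ej[lo]);
          if (den2 > 0.0) {
            acc[n] += (cc[hi + 1] - cc[lo]) / std::sqrt(den2);
          }
        }
      }
      const double inv = 1.0 / (N - m);
      double *pm = po + (static_cast<R_xlen_t>(m - 1) * L + l) * nt;
      for (int n = 0; n < nt; ++n) pm[n] = acc[n] * inv;
    }
  }
  out.attr("dim") = IntegerVector::create(nt, L, M);
  return out;
}
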