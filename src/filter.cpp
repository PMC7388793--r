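#include <Rcpp.h>
using namespace Rcpp;

// One IIR pass (direct form II transposed) over a buffer, in place.
// dir = +1 forward, -1 backward. State z is seeded by the caller.
static inline void df2t_pass(const double* b, const double* a, int nf,
                             double* buf, int n, double* z, int dir) {
  const int ns = nf - 1;
  int t = dir > 0 ? 0 : n - 1;
  if (nf == 7) {                      // unrolled order-3 band-pass case
    double z0 = z[0], z1 = z[1], z2 = z[2], z3 = z[3], z4 = z[4], z5 = z[5];
    const double b0 = b[0], b1 = b[1], b2 = b[2], b3 = b[3], b4 = b[4],
                 b5 = b[5], b6 = b[6];
    const double a1 = a[1], a2 = a[2], a3 = a[3], a4 = a[4], a5 = a[5],
                 a6 = a[6];
    for (int i = 0; i < n; ++i, t += dir) {
      const double xt = buf[t];
      const double yt = b0 * xt + z0;
      z0 = b1 * xt + z1 - a1 * yt;
      z1 = b2 * xt + z2 - a2 * yt;
      z2 = b3 * xt + z3 - a3 * yt;
      z3 = b4 * xt + z4 - a4 * yt;
      z4 = b5 * xt + z5 - a5 * yt;
      z5 = b6 * xt - a6 * yt;
      buf[t] = yt;
    }
    z[0] = z0; z[1] = z1; z[2] = z2; z[3] = z3; z[4] = z4; z[5] = z5;
  } else {
    for (int i = 0; i < n; ++i, t += dir) {
      const double xt = buf[t];
      const double yt = b[0] * xt + z[0];
      for (int k = 0; k < ns - 1; ++k)
        z[k] = b[k + 1] * xt + z[k + 1] - a[k + 1] * yt;
      z[ns - 1] = b[nf - 1] * xt - a[nf - 1] * yt;
      buf[t] = yt;
    }
  }
}

// Zero-phase (forward-backward) IIR filter down each column of x, with
// odd-reflection padding of `padlen` samples at both ends and steady-state
// initial conditions zi (per unit step; scaled by the edge sample).
// Coefficients must be normalized so a[0] == 1.
// [[Rcpp::export]]
NumericMatrix filtfilt_cpp(NumericVector b, NumericVector a, NumericMatrix x,
                           NumericVector zi_unit, int padlen) {
  const int n = x.nrow(), m = x.ncol();
  const int nf = std::max(a.size(), b.size());
  const int ns = nf - 1;
  if (zi_unit.size() != ns) stop("zi_unit must have length(filter) - 1");
  if (n <= padlen + 1) stop("signal too short for zero-phase filtering");
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];

  NumericMatrix y(n, m);
  const int np = n + 2 * padlen;
  std::vector<double> buf(np), z(ns);
  for (int c = 0; c < m; ++c) {
    const double* xc = x.begin() + (size_t)c * n;
    // odd reflection about both end points
    for (int i = 0; i < padlen; ++i) buf[i] = 2.0 * xc[0] - xc[padlen - i];
    std::copy(xc, xc + n, buf.begin() + padlen);
    for (int i = 0; i < padlen; ++i)
      buf[padlen + n + i] = 2.0 * xc[n - 1] - xc[n - 2 - i];
    // forward pass
    for (int k = 0; k < ns; ++k) z[k] = zi_unit[k] * buf[0];
    df2t_pass(bb.data(), aa.data(), nf, buf.data(), np, z.data(), +1);
    // backward pass
    for (int k = 0; k < ns; ++k) z[k] = zi_unit[k] * buf[np - 1];
    df2t_pass(bb.data(), aa.data(), nf, buf.data(), np, z.data(), -1);
    std::copy(buf.begin() + padlen, buf.begin() + padlen + n,
              y.begin() + (size_t)c * n);
  }
  return y;
}
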