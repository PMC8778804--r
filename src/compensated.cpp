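#include <Rcpp.h>
using namespace Rcpp;

// Neumaier (improved Kahan) compensated summation. Every mass/moment
// accumulation in the package routes through these so that conservation
// identities (segment masses vs total, profile sums vs parent MoI) hold to
// ~1e-15 relative instead of drifting with vector length.

static inline double neumaier(const double* x, R_xlen_t n) {
  double s = 0.0, c = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double t = s + x[i];
    if (std::abs(s) >= std::abs(x[i]))
      c += (s - t) + x[i];
    else
      c += (x[i] - t) + s;
    s = t;
  }
  return s + c;
}

// [[Rcpp::export]]
double compensated_sum(NumericVector x) {
  return neumaier(REAL(x), x.size());
}

// sum(x * w) with a single compensated accumulator (no intermediate vector)
// [[Rcpp::export]]
double compensated_dot(NumericVector x, NumericVector w) {
  R_xlen_t n = x.size();
  if (w.size() != n) stop("length mismatch");
  double s = 0.0, c = 0.0;
  const double* xp = REAL(x); const double* wp = REAL(w);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = xp[i] * wp[i];
    double t = s + v;
    if (std::abs(s) >= std::abs(v)) c += (s - t) + v; else c += (v - t) + s;
    s = t;
  }
  return s + c;
}

// group-wise compensated sums: sums x by integer group id in [1, ngroups]
// (ids outside the range are ignored)
// [[Rcpp::export]]
NumericVector compensated_group_sum(NumericVector x, IntegerVector g, int ngroups) {
  R_xlen_t n = x.size();
  if (g.size() != n) stop("length mismatch");
  NumericVector s(ngroups), c(ngroups);
  for (R_xlen_t i = 0; i < n; ++i) {
    int k = g[i];
    if (k < 1 || k > ngroups) continue;
    double v = x[i];
    double t = s[k - 1] + v;
    if (std::abs(s[k - 1]) >= std::abs(v)) c[k - 1] += (s[k - 1] - t) + v;
    else c[k - 1] += (v - t) + s[k - 1];
    s[k - 1] = t;
  }
  for (int k = 0; k < ngroups; ++k) s[k] += c[k];
  return s;
}
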