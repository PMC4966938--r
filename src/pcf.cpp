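#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact penalized least-squares segmentation (piecewise constant fitting).
//
// Minimizes  sum_segments sum_samples SSE(segment, sample)
//            + gamma * (number of segments - 1)
// subject to every segment containing at least kmin probes, by O(n^2)
// dynamic programming over the last-segment start. With one sample this is
// single-sample PCF; with several columns it is the joint (shared-breakpoint)
// multi-sample fit, since the within-segment cost is additive over samples.
//
// y: n x S matrix of (winsorized) log-ratios for one chromosome.
// Returns 1-based probe index starts of each segment.
// [[Rcpp::export(name = ".pcf_dp")]]
IntegerVector pcf_dp(NumericMatrix y, double gamma, int kmin) {
  const int n = y.nrow(), S = y.ncol();
  if (n == 0) return IntegerVector(0);
  if (kmin < 1) stop("kmin must be >= 1");
  if (n < kmin) {  // degenerate: a single segment is the only option
    IntegerVector out(1); out[0] = 1; return out;
  }
  // cumulative sums per sample
  std::vector<std::vector<double> > c1(S, std::vector<double>(n + 1, 0.0));
  std::vector<std::vector<double> > c2(S, std::vector<double>(n + 1, 0.0));
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < n; ++i) {
      const double v = y(i, s);
      c1[s][i + 1] = c1[s][i] + v;
      c2[s][i + 1] = c2[s][i] + v * v;
    }
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> F(n + 1, INF);
  std::vector<int> from(n + 1, 0);
  F[0] = 0.0;
  for (int j = kmin; j <= n; ++j) {
    double best = INF; int argi = 1;
    // last segment covers probes i..j (1-based), length >= kmin
    for (int i = 1; i + kmin - 1 <= j; ++i) {
      if (!std::isfinite(F[i - 1])) continue;
      const double len = j - i + 1;
      double cost = 0.0;
      for (int s = 0; s < S; ++s) {
        const double s1 = c1[s][j] - c1[s][i - 1];
        const double s2 = c2[s][j] - c2[s][i - 1];
        cost += s2 - s1 * s1 / len;
      }
      const double val = F[i - 1] + cost + gamma;
      if (val < best - 1e-12 ||
          (std::abs(val - best) <= 1e-12 && i < argi)) {
        best = val; argi = i;
      }
    }
    F[j] = best; from[j] = argi;
  }
  // backtrack segment starts
  std::vector<int> starts;
  int j = n;
  while (j > 0) { starts.push_back(from[j]); j = from[j] - 1; }
  std::reverse(starts.begin(), starts.end());
  return wrap(starts);
}

// Windowed winsorization: clamp each value to running median +/- tau * MAD
// (MAD scaled by 1.4826), computed in a centered window of k probes
// truncated at chromosome ends.
// [[Rcpp::export(name = ".winsorize_window")]]
NumericVector winsorize_window(NumericVector x, int k, double tau) {
  const int n = x.size();
  NumericVector out(n);
  const int half = k / 2;
  std::vector<double> buf;
  buf.reserve(k);
  for (int i = 0; i < n; ++i) {
    const int lo = std::max(0, i - half), hi = std::min(n - 1, i + half);
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    const int m = buf.size(), mid = m / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double med = buf[mid];
    if (m % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
      med = 0.5 * (med + buf[mid - 1]);
    }
    for (int t = 0; t < m; ++t) buf[t] = std::abs(buf[t] - med);
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double mad = buf[mid];
    if (m % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
      mad = 0.5 * (mad + buf[mid - 1]);
    }
    const double s = 1.4826 * mad;
    const double loB = med - tau * s, hiB = med + tau * s;
    out[i] = std::min(std::max(x[i], loB), hiB);
  }
  return out;
}
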