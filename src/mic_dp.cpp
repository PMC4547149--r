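#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Optimal partition of the free axis given fixed bins on the other axis.
// `ub`: 1-based fixed-axis bin label of every point, in free-axis order.
// Boundaries are restricted to clump edges (runs of equal label), which is
// lossless for the optimum; if the clump count exceeds `max_clumps`
// (heuristic mode) neighbouring clumps are merged into equal-count
// superclumps first. Returns the maximum mutual information (bits) over
// partitions of the free axis into at most `maxl` bins.
// [[Rcpp::export]]
double cpp_mic_dp(const IntegerVector& ub, int q, int maxl, int max_clumps) {
  const int n = ub.size();

  // clumps: maximal runs of equal label
  std::vector<int> ends;
  for (int i = 1; i < n; ++i) {
    if (ub[i] != ub[i - 1]) ends.push_back(i);  // end index (exclusive)
  }
  ends.push_back(n);
  int m = (int)ends.size();

  // superclump merge (heuristic path)
  if (max_clumps > 0 && m > max_clumps) {
    double tgt = (double)n / max_clumps;
    std::vector<int> keep;
    int prev = 0;
    double acc = 0.0;
    for (int t = 0; t < m; ++t) {
      acc += ends[t] - prev;
      prev = ends[t];
      if (acc >= tgt || t == m - 1) {
        keep.push_back(ends[t]);
        acc = 0.0;
      }
    }
    ends = keep;
    m = (int)ends.size();
  }

  // prefix counts: pref[(t) * q + b] = count of label b+1 in clumps 0..t-1
  std::vector<int> pref((m + 1) * q, 0);
  {
    int start = 0;
    for (int t = 0; t < m; ++t) {
      for (int b = 0; b < q; ++b) pref[(t + 1) * q + b] = pref[t * q + b];
      for (int i = start; i < ends[t]; ++i) pref[(t + 1) * q + ub[i] - 1]++;
      start = ends[t];
    }
  }

  const double L2 = std::log(2.0);
  // score of merging clumps (a, b]: sum_q cnt * log2(cnt / cb)
  auto seg = [&](int a, int b) {
    double cb = 0.0, s = 0.0;
    for (int k = 0; k < q; ++k) {
      cb += pref[b * q + k] - pref[a * q + k];
    }
    if (cb <= 0.0) return 0.0;
    for (int k = 0; k < q; ++k) {
      double c = pref[b * q + k] - pref[a * q + k];
      if (c > 0.0) s += c * std::log(c / cb) / L2;
    }
    return s;
  };

  int lmax = std::min(maxl, m);
  std::vector<double> prev_best(m + 1), cur(m + 1);
  for (int t = 1; t <= m; ++t) prev_best[t] = seg(0, t);
  double best_final = prev_best[m];
  for (int l = 2; l <= lmax; ++l) {
    for (int t = 1; t <= m; ++t) cur[t] = R_NegInf;
    for (int t = l; t <= m; ++t) {
      double v = R_NegInf;
      for (int s2 = l - 1; s2 <= t - 1; ++s2) {
        double cand = prev_best[s2] + seg(s2, t);
        if (cand > v) v = cand;
      }
      cur[t] = v;
    }
    if (cur[m] > best_final) best_final = cur[m];
    std::swap(prev_best, cur);
  }

  double hq = 0.0;
  for (int k = 0; k < q; ++k) {
    double c = pref[m * q + k];
    if (c > 0.0) hq -= (c / n) * std::log(c / n) / L2;
  }
  return hq + best_final / n;
}
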