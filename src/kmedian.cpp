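#include <Rcpp.h>
#include <vector>
#include <functional>
#include <algorithm>
using namespace Rcpp;

// Exact k-median on a dense symmetric distance matrix by exhaustive
// enumeration of all k-subsets in lexicographic order, with two prunings
// that never cut an improving (or first-equal) subtree:
//   * a deterministic greedy forward-selection upper bound to start from,
//   * a per-point lower bound sum_i min(curmin_i, suffmin_c[i]) where
//     suffmin_c[i] = min_{j >= c} D(i, j); the bound is non-decreasing in c,
//     so once it exceeds the incumbent the remaining siblings can be skipped.
// Among objective-equal optima (up to a relative tolerance) the
// lexicographically smallest index tuple is returned: enumeration visits
// tuples in that order and later ties never replace the incumbent.
// Negative off-diagonal distances are legal (amplified commute distance can
// produce them on degenerate graphs).
// [[Rcpp::export]]
List kmedian_enumerate_cpp(NumericMatrix D, int k) {
  const int m = D.nrow();
  if (D.ncol() != m) stop("distance matrix must be square");
  if (k < 1 || k > m) stop("k out of range");

  // greedy forward selection for an initial upper bound (deterministic)
  std::vector<double> gmin(m, R_PosInf);
  {
    std::vector<bool> used(m, false);
    for (int step = 0; step < k; ++step) {
      int bestj = -1;
      double bestval = R_PosInf;
      for (int j = 0; j < m; ++j) {
        if (used[j]) continue;
        double tot = 0.0;
        const double* col = &D(0, j);
        for (int i = 0; i < m; ++i) tot += std::min(gmin[i], col[i]);
        if (tot < bestval) { bestval = tot; bestj = j; }
      }
      used[bestj] = true;
      const double* col = &D(0, bestj);
      for (int i = 0; i < m; ++i) gmin[i] = std::min(gmin[i], col[i]);
    }
  }
  double greedy_obj = 0.0;
  for (int i = 0; i < m; ++i) greedy_obj += gmin[i];

  // suffix minima, laid out per candidate column: suf[c][i] = min_{j>=c} D(i,j)
  std::vector<double> suf((size_t)m * m);
  {
    double* last = &suf[(size_t)(m - 1) * m];
    const double* dl = &D(0, m - 1);
    for (int i = 0; i < m; ++i) last[i] = dl[i];
    for (int c = m - 2; c >= 0; --c) {
      double* cur = &suf[(size_t)c * m];
      const double* nxt = &suf[(size_t)(c + 1) * m];
      const double* dc = &D(0, c);
      for (int i = 0; i < m; ++i) cur[i] = std::min(nxt[i], dc[i]);
    }
  }

  const double rel = 1e-9;
  auto tol_at = [rel](double x) { return rel * (1.0 + std::fabs(x)); };

  // seeded above the greedy optimum so the first (lexicographically
  // smallest) optimal set is still accepted by the strict improvement test
  double best = greedy_obj + 3.0 * tol_at(greedy_obj);
  std::vector<int> best_set;
  std::vector<int> cur_set(k);
  // mins[l] = elementwise min distance to the first l chosen medoids
  std::vector<std::vector<double>> mins(k + 1, std::vector<double>(m));
  std::fill(mins[0].begin(), mins[0].end(), R_PosInf);

  std::function<void(int, int)> rec = [&](int level, int start) {
    const double* cm = mins[level].data();
    if (level == k - 1) {
      // last medoid: evaluate leaves directly, bound fused into the same pass
      for (int c = start; c < m; ++c) {
        const double* dc = &D(0, c);
        const double* sf = &suf[(size_t)c * m];
        double tot = 0.0, lb = 0.0;
        for (int i = 0; i < m; ++i) {
          const double cmi = cm[i];
          tot += std::min(cmi, dc[i]);
          lb += std::min(cmi, sf[i]);
        }
        if (tot < best - tol_at(tot)) {
          best = tot;
          cur_set[level] = c;
          best_set.assign(cur_set.begin(), cur_set.end());
        }
        if (lb > best - tol_at(best)) break;  // bound non-decreasing in c
      }
      return;
    }
    for (int c = start; c <= m - (k - level); ++c) {
      const double* sf = &suf[(size_t)c * m];
      double lb = 0.0;
      for (int i = 0; i < m; ++i) lb += std::min(cm[i], sf[i]);
      if (lb > best - tol_at(best)) break;
      cur_set[level] = c;
      double* nm = mins[level + 1].data();
      const double* dc = &D(0, c);
      for (int i = 0; i < m; ++i) nm[i] = std::min(cm[i], dc[i]);
      rec(level + 1, c + 1);
    }
  };
  rec(0, 0);

  if (best_set.empty()) stop("internal error: no medoid set found");
  IntegerVector med(best_set.begin(), best_set.end());
  double obj = 0.0;
  {
    std::vector<double> mn(m, R_PosInf);
    for (int j : best_set) {
      const double* dc = &D(0, j);
      for (int i = 0; i < m; ++i) mn[i] = std::min(mn[i], dc[i]);
    }
    for (int i = 0; i < m; ++i) obj += mn[i];
  }
  return List::create(_["medoids"] = med + 1, _["objective"] = obj);
}
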