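#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap costs.
// Scoring: match +1, mismatch -1, gap -2 per gapped column.
// Traceback prefers diagonal, then up, then left, so the reported
// alignment is deterministic among co-optimal paths.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b,
              int match = 1, int mismatch = -1, int gap = -2) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  // full DP matrix for traceback; sequences here are fixture-scale (<= few kb)
  std::vector<signed char> tb((n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = j * gap; tb[j] = 2; }
  tb[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    tb[i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      int sup = prev[j] + gap;
      int sleft = cur[j - 1] + gap;
      int best = sdiag; signed char dir = 0;
      if (sup > best) { best = sup; dir = 1; }
      if (sleft > best) { best = sleft; dir = 2; }
      cur[j] = best;
      tb[i * (m + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }
  int score = prev[m];
  int i = n, j = m, matches = 0, mismatches = 0, gaps = 0;
  while (i > 0 || j > 0) {
    signed char dir = tb[i * (m + 1) + j];
    if (i > 0 && j > 0 && dir == 0) {
      if (a[i - 1] == b[j - 1]) ++matches; else ++mismatches;
      --i; --j;
    } else if (i > 0 && (dir == 1 || j == 0)) {
      ++gaps; --i;
    } else {
      ++gaps; --j;
    }
  }
  int columns = matches + mismatches + gaps;
  return List::create(
    _["score"] = score,
    _["matches"] = matches,
    _["mismatches"] = mismatches,
    _["gaps"] = gaps,
    _["columns"] = columns,
    _["identity"] = columns > 0 ? (double)matches / columns : 1.0);
}
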