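#include <Rcpp.h>
using namespace Rcpp;

// End-to-end alignment with unit costs for substitutions and gaps
// (terminal gaps included). Among minimum-cost alignments the tie-break
// is: more matches, then fewer gaps. Returns (matches, mismatches, gaps)
// or all -1 when the minimum cost exceeds max_dist.
//
// The DP tracks, per cell, the lexicographic optimum of
// (cost, -matches, gaps); all three components are additive along an
// alignment path, so cell-local comparison yields the global optimum.

struct Cell {
  int cost;
  int matches;
  int gaps;
};

static inline bool better(const Cell& a, const Cell& b) {
  if (a.cost != b.cost) return a.cost < b.cost;
  if (a.matches != b.matches) return a.matches > b.matches;
  return a.gaps < b.gaps;
}

// [[Rcpp::export(name = ".align_budget_cpp")]]
IntegerVector align_budget_cpp(IntegerVector q, IntegerVector r, int max_dist) {
  const int n = q.size(), m = r.size();
  std::vector<Cell> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = {j, 0, j};
  for (int i = 1; i <= n; ++i) {
    cur[0] = {i, 0, i};
    for (int j = 1; j <= m; ++j) {
      bool match = (q[i - 1] == r[j - 1]) && (q[i - 1] != NA_INTEGER);
      Cell diag = prev[j - 1];
      diag.cost += match ? 0 : 1;
      diag.matches += match ? 1 : 0;
      Cell up = prev[j];   up.cost += 1; up.gaps += 1;
      Cell left = cur[j - 1]; left.cost += 1; left.gaps += 1;
      Cell best = diag;
      if (better(up, best)) best = up;
      if (better(left, best)) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  Cell fin = prev[m];
  if (fin.cost > max_dist) return IntegerVector::create(-1, -1, -1);
  int mismatches = fin.cost - fin.gaps;
  return IntegerVector::create(fin.matches, mismatches, fin.gaps);
}
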