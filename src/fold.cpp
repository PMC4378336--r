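#include <Rcpp.h>
using namespace Rcpp;

// Minimum free energy over multibranch-free (single-stem) nested
// structures: a structure is a chain of base pairs
// (i1,j1) > (i2,j2) > ... > (ik,jk) closed by a hairpin loop of >=
// min_loop unpaired bases, with bulges / internal loops of total size
// <= max_interior between consecutive pairs. Energy = sum of stacking
// terms (adjacent pairs), loop penalties and a per-pair bonus
// (0 in the thermodynamic model; -1 in the unit model used for
// cross-checks against the Nussinov recursion).
//
// Ties are broken toward fewer pairs, then the lexicographically
// smallest (k,l) choice, so the fold is fully deterministic.

static const double INF = 1e9;
static const double EPS = 1e-9;

// base codes: A=1 C=2 G=3 U=4 -> pair types AU=0 UA=1 CG=2 GC=3 GU=4 UG=5
static inline int pair_type(int a, int b) {
  if (a == 1 && b == 4) return 0;
  if (a == 4 && b == 1) return 1;
  if (a == 2 && b == 3) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 3 && b == 4) return 4;
  if (a == 4 && b == 3) return 5;
  return -1;
}

// [[Rcpp::export(name = ".fold_stem_cpp")]]
List fold_stem_cpp(IntegerVector seq, NumericMatrix stack,
                   NumericVector hairpin_pen, NumericVector bulge_pen,
                   NumericVector internal_pen, double pair_bonus,
                   int min_loop, int max_interior) {
  const int n = seq.size();
  std::vector<double> V((size_t)n * n, INF);
  std::vector<int> NP((size_t)n * n, 0);
  std::vector<int> CK((size_t)n * n, -1), CL((size_t)n * n, -1);
  std::vector<int> pt(n * (size_t)n, -1);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      pt[(size_t)i * n + j] = pair_type(seq[i], seq[j]);

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      size_t ij = (size_t)i * n + j;
      if (pt[ij] < 0) continue;
      // hairpin closing
      int hs = j - i - 1;
      double best = INF;
      int bnp = 0, bk = -1, bl = -1;
      if (hs >= min_loop && hs < (int)hairpin_pen.size()) {
        best = hairpin_pen[hs] + pair_bonus;
        bnp = 1;
      }
      // interior extension to inner pair (k,l)
      int kmax = std::min(j - 1, i + max_interior + 1);
      for (int k = i + 1; k <= kmax; ++k) {
        int s1 = k - i - 1;
        int lmin = std::max(k + min_loop + 1, j - 1 - (max_interior - s1));
        for (int l = j - 1; l >= lmin; --l) {
          size_t kl = (size_t)k * n + l;
          if (V[kl] >= INF / 2) continue;
          int s2 = j - l - 1;
          double cost;
          if (s1 == 0 && s2 == 0) {
            cost = stack(pt[ij], pt[kl]);
          } else if (s1 == 0 || s2 == 0) {
            int s = s1 + s2;
            cost = (s < (int)bulge_pen.size()) ? bulge_pen[s] : INF;
          } else {
            int s = s1 + s2;
            cost = (s < (int)internal_pen.size()) ? internal_pen[s] : INF;
          }
          if (cost >= INF / 2) continue;
          double e = V[kl] + pair_bonus + cost;
          int np = NP[kl] + 1;
          bool take = false;
          if (e < best - EPS) take = true;
          else if (e < best + EPS) {
            if (np < bnp) take = true;
            else if (np == bnp && (bk == -1 || k < bk || (k == bk && l < bl))) take = true;
          }
          if (take) { best = e; bnp = np; bk = k; bl = l; }
        }
      }
      V[ij] = best;
      NP[ij] = bnp;
      CK[ij] = bk;
      CL[ij] = bl;
    }
  }

  // pick outermost pair (or the empty structure)
  double best = 0.0;
  int bnp = 0, bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      size_t ij = (size_t)i * n + j;
      if (V[ij] >= INF / 2) continue;
      bool take = false;
      if (V[ij] < best - EPS) take = true;
      else if (V[ij] < best + EPS && bi != -1) {
        if (NP[ij] < bnp) take = true;
        else if (NP[ij] == bnp && (i < bi || (i == bi && j < bj))) take = true;
      }
      if (take) { best = V[ij]; bnp = NP[ij]; bi = i; bj = j; }
    }
  }

  IntegerVector partner(n, 0);
  double mfe = 0.0;
  if (bi >= 0) {
    mfe = best;
    int i = bi, j = bj;
    while (i >= 0) {
      partner[i] = j + 1;  // 1-based
      partner[j] = i + 1;
      size_t ij = (size_t)i * n + j;
      int k = CK[ij], l = CL[ij];
      i = k; j = l;
    }
  }
  return List::create(_["mfe"] = mfe, _["partner"] = partner);
}
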