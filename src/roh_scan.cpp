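#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// One chromosome of one individual. g: genotype codes 0/1/2, -1 = missing.
// pos: base-pair positions, strictly increasing. Returns the selected ROH
// segments as a matrix with columns (i, j, n_het, n_missing), i/j 0-based
// SNP indices of the run endpoints, ordered by start.
//
// A candidate interval [i, j] qualifies when: both endpoints are
// homozygous calls; length_bp = pos[j]-pos[i]+1 >= min_length_bp;
// n_snps >= l_min_snps; every internal adjacent gap <= max_gap_bp;
// n_snps / length_bp >= min_density; and the heterozygous/missing call
// counts do not exceed the allowance of the interval's length class.
// Maximal qualifying intervals (no qualifying strict superinterval) are
// enumerated, then kept longest-first (ties: leftmost), dropping overlaps.
//
// Search strategy: for each start i the largest feasible end hi(i) is the
// minimum of a two-pointer budget bound (het/miss counts within (i, j]
// never exceed the largest class allowance; monotone in i) and the first
// oversized inter-SNP gap after i. Ends are scanned downward from hi(i),
// each candidate checked in O(1) via prefix counts. Only ends beyond the
// running maximum of previous feasible ends can produce maximal
// intervals, so the downward scan stops there; this keeps the whole scan
// near-linear even inside megabase-scale homozygous tracts.
// [[Rcpp::export]]
IntegerMatrix roh_scan_chr(IntegerVector g, NumericVector pos,
                           double min_length_bp, int l_min_snps,
                           double max_gap_bp, double min_density,
                           NumericVector class_edges_bp,
                           IntegerVector het_allow,
                           IntegerVector miss_allow) {
  const int n = g.size();
  const int ncls = class_edges_bp.size();
  int het_cap = 0, miss_cap = 0;
  for (int k = 0; k < ncls; ++k) {
    het_cap = std::max(het_cap, het_allow[k]);
    miss_cap = std::max(miss_cap, miss_allow[k]);
  }
  if (n < 2 || n < l_min_snps) return IntegerMatrix(0, 4);

  // prefix counts: chet[j] = heterozygous calls among SNPs 0..j-1
  std::vector<int> chet(n + 1, 0), cmiss(n + 1, 0);
  for (int t = 0; t < n; ++t) {
    chet[t + 1] = chet[t] + (g[t] == 1 ? 1 : 0);
    cmiss[t + 1] = cmiss[t] + (g[t] == -1 ? 1 : 0);
  }
  // gap_end[i]: largest j reachable from i without an oversized gap
  std::vector<int> gap_end(n);
  gap_end[n - 1] = n - 1;
  for (int t = n - 2; t >= 0; --t)
    gap_end[t] = (pos[t + 1] - pos[t] > max_gap_bp) ? t : gap_end[t + 1];

  struct Seg { int i, j, nhet, nmiss; double len; };
  std::vector<Seg> maximal;
  int run_max = -1;   // largest qualifying end seen so far
  int budget_end = 0; // two-pointer bound, non-decreasing in i
  for (int i = 0; i < n; ++i) {
    if (budget_end < i) budget_end = i;
    while (budget_end + 1 < n &&
           chet[budget_end + 2] - chet[i + 1] <= het_cap &&
           cmiss[budget_end + 2] - cmiss[i + 1] <= miss_cap)
      ++budget_end;
    if (g[i] != 0 && g[i] != 2) continue;  // endpoint must be homozygous
    int hi = std::min(budget_end, gap_end[i]);
    int lo = std::max(i + l_min_snps - 1, run_max + 1);
    int found = -1;
    for (int j = hi; j >= lo; --j) {
      if (g[j] != 0 && g[j] != 2) continue;
      double len = pos[j] - pos[i] + 1.0;
      if (len < min_length_bp) break;  // only shrinks further down
      int nsnp = j - i + 1;
      if ((double)nsnp / len < min_density) continue;
      int nhet = chet[j + 1] - chet[i];
      int nmiss = cmiss[j + 1] - cmiss[i];
      int cls = 0;
      while (cls + 1 < ncls && len >= class_edges_bp[cls + 1]) ++cls;
      if (nhet > het_allow[cls] || nmiss > miss_allow[cls]) continue;
      found = j;
      break;
    }
    if (found >= 0) {
      // found > run_max, so [i, found] is contained in no earlier
      // qualifying interval and is right-maximal for this start
      Seg s;
      s.i = i;
      s.j = found;
      s.nhet = chet[found + 1] - chet[i];
      s.nmiss = cmiss[found + 1] - cmiss[i];
      s.len = pos[found] - pos[i] + 1.0;
      maximal.push_back(s);
      run_max = found;
    }
  }

  // longest-first selection, leftmost on ties, drop overlaps
  std::vector<int> ord(maximal.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = (int)k;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (maximal[a].len != maximal[b].len)
      return maximal[a].len > maximal[b].len;
    return maximal[a].i < maximal[b].i;
  });
  std::vector<int> kept;
  for (int k : ord) {
    bool clash = false;
    for (int q : kept) {
      if (maximal[k].i <= maximal[q].j && maximal[q].i <= maximal[k].j) {
        clash = true;
        break;
      }
    }
    if (!clash) kept.push_back(k);
  }
  std::sort(kept.begin(), kept.end(), [&](int a, int b) {
    return maximal[a].i < maximal[b].i;
  });
  IntegerMatrix out(kept.size(), 4);
  for (size_t r = 0; r < kept.size(); ++r) {
    const Seg &s = maximal[kept[r]];
    out(r, 0) = s.i;
    out(r, 1) = s.j;
    out(r, 2) = s.nhet;
    out(r, 3) = s.nmiss;
  }
  return out;
}
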