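#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Haplotypes are stored as a (2N x L) raw matrix of 0/1 allele bytes; the
// two rows 2i, 2i+1 are individual i's maternal/paternal haplotypes.
// Recombination: per gamete and chromosome, a Poisson(len_M) number of
// crossovers placed uniformly, no interference; the copied strand starts
// at random and switches at each crossover. All randomness comes from the
// R RNG, so set.seed() in R makes runs reproducible.

static inline void make_gamete(const unsigned char *h0,
                               const unsigned char *h1,
                               unsigned char *out,
                               const std::vector<int> &chr_start,
                               const std::vector<double> &gpos,
                               const std::vector<double> &chr_len,
                               std::vector<double> &xbuf) {
  const int nchr = (int)chr_len.size();
  for (int c = 0; c < nchr; ++c) {
    const int s = chr_start[c], e = chr_start[c + 1];
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    int k = (int)R::rpois(chr_len[c]);
    if (k <= 0) {
      const unsigned char *src = cur ? h1 : h0;
      for (int t = s; t < e; ++t) out[t] = src[t];
      continue;
    }
    xbuf.resize(k);
    for (int x = 0; x < k; ++x) xbuf[x] = unif_rand() * chr_len[c];
    std::sort(xbuf.begin(), xbuf.end());
    int xi = 0;
    for (int t = s; t < e; ++t) {
      while (xi < k && xbuf[xi] <= gpos[t]) {
        cur ^= 1;
        ++xi;
      }
      out[t] = cur ? h1[t] : h0[t];
    }
  }
}

static void unpack_layout(IntegerVector chr_start_r, NumericVector gpos_r,
                          NumericVector chr_len_r,
                          std::vector<int> &chr_start,
                          std::vector<double> &gpos,
                          std::vector<double> &chr_len) {
  chr_start.assign(chr_start_r.begin(), chr_start_r.end());
  gpos.assign(gpos_r.begin(), gpos_r.end());
  chr_len.assign(chr_len_r.begin(), chr_len_r.end());
}

// Evolve a population forward. hap: founder haplotypes (2*N0 x L).
// chr_start: 0-based SNP start index per chromosome, length nchr+1 with
// the SNP count appended. gpos: genetic position (Morgans) of each SNP
// within its chromosome. chr_len: chromosome lengths in Morgans.
// schedule: diploid population size for each generation to simulate.
// Mating is Wright-Fisher with random parent pairs, selfing excluded.
// [[Rcpp::export]]
RawMatrix wf_evolve(RawMatrix hap, IntegerVector chr_start,
                    NumericVector gpos, NumericVector chr_len,
                    IntegerVector schedule) {
  const int L = hap.ncol();
  if ((int)gpos.size() != L) stop("gpos length must equal SNP count");
  if (hap.nrow() % 2 != 0) stop("haplotype rows must come in pairs");
  int ncur = hap.nrow() / 2;
  if (ncur < 2) stop("need at least 2 founder individuals");
  std::vector<int> cs;
  std::vector<double> gp, cl;
  unpack_layout(chr_start, gpos, chr_len, cs, gp, cl);

  std::vector<unsigned char> cur((size_t)2 * ncur * L);
  for (int r = 0; r < 2 * ncur; ++r)
    for (int t = 0; t < L; ++t)
      cur[(size_t)r * L + t] = hap(r, t);

  std::vector<unsigned char> nxt;
  std::vector<double> xbuf;
  for (int gen = 0; gen < schedule.size(); ++gen) {
    const int nnew = schedule[gen];
    if (nnew < 2) stop("population size below 2 in schedule");
    nxt.assign((size_t)2 * nnew * L, 0);
    for (int i = 0; i < nnew; ++i) {
      int mo = (int)(unif_rand() * ncur);
      if (mo >= ncur) mo = ncur - 1;
      int fa = (int)(unif_rand() * (ncur - 1));
      if (fa >= ncur - 1) fa = ncur - 2;
      if (fa >= mo) ++fa;  // distinct parents
      make_gamete(&cur[(size_t)(2 * mo) * L], &cur[(size_t)(2 * mo + 1) * L],
                  &nxt[(size_t)(2 * i) * L], cs, gp, cl, xbuf);
      make_gamete(&cur[(size_t)(2 * fa) * L], &cur[(size_t)(2 * fa + 1) * L],
                  &nxt[(size_t)(2 * i + 1) * L], cs, gp, cl, xbuf);
    }
    cur.swap(nxt);
    ncur = nnew;
  }
  RawMatrix out(2 * ncur, L);
  for (int r = 0; r < 2 * ncur; ++r)
    for (int t = 0; t < L; ++t)
      out(r, t) = cur[(size_t)r * L + t];
  return out;
}

// Offspring of designated parent pairs. parents: k x 2 matrix of 0-based
// individual indices into hap's 2-row pairs. Row 2i of the result is a
// gamete of parents(i,0), row 2i+1 of parents(i,1).
// [[Rcpp::export]]
RawMatrix wf_offspring(RawMatrix hap, IntegerMatrix parents,
                       IntegerVector chr_start, NumericVector gpos,
                       NumericVector chr_len) {
  const int L = hap.ncol();
  const int k = parents.nrow();
  const int nind = hap.nrow() / 2;
  std::vector<int> cs;
  std::vector<double> gp, cl;
  unpack_layout(chr_start, gpos, chr_len, cs, gp, cl);
  std::vector<unsigned char> src((size_t)hap.nrow() * L);
  for (int r = 0; r < hap.nrow(); ++r)
    for (int t = 0; t < L; ++t)
      src[(size_t)r * L + t] = hap(r, t);
  RawMatrix out(2 * k, L);
  std::vector<unsigned char> buf(L);
  std::vector<double> xbuf;
  for (int i = 0; i < k; ++i) {
    for (int side = 0; side < 2; ++side) {
      int p = parents(i, side);
      if (p < 0 || p >= nind) stop("parent index out of range");
      make_gamete(&src[(size_t)(2 * p) * L], &src[(size_t)(2 * p + 1) * L],
                  buf.data(), cs, gp, cl, xbuf);
      for (int t = 0; t < L; ++t) out(2 * i + side, t) = buf[t];
    }
  }
  return out;
}
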