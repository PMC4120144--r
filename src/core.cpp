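// Compiled core: FM-index pair, bounded edit distance, randomized
// seed-and-extend alignment loop, suffix-array repeat density.
//
// Alphabet codes (lexicographic, matching ASCII order of the letters):
//   $ = 0, A = 1, C = 2, G = 3, N = 4, T = 5
// N is stored in the text (coordinates preserved) but never matched
// during search, so seeds cannot span an N.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static const int SIGMA = 6;
static const int CKP = 128;  // occ checkpoint spacing

static inline int code_of(char c) {
  switch (c) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 3;
    case 'N': return 4;
    case 'T': return 5;
    default: return -1;
  }
}

static inline char comp_of(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_of(s[i]);
  return out;
}

// ---------------------------------------------------------------- suffix array
// Prefix-doubling construction, O(n log^2 n): safe on highly repetitive
// inputs where direct suffix comparison degenerates.
static std::vector<int> build_sa(const std::vector<uint8_t>& s) {
  const int n = (int)s.size();
  std::vector<int> sa(n), rnk(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rnk[i] = s[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = a + k < n ? rnk[a + k] : -1;
      int rb = b + k < n ? rnk[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// Kasai's algorithm; lcp[r] = LCP(suffix at rank r-1, suffix at rank r), lcp[0]=0.
static std::vector<int> build_lcp(const std::vector<uint8_t>& s,
                                  const std::vector<int>& sa) {
  const int n = (int)s.size();
  std::vector<int> rank_(n), lcp(n, 0);
  for (int i = 0; i < n; ++i) rank_[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank_[i] > 0) {
      int j = sa[rank_[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[rank_[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return lcp;
}

// ------------------------------------------------------------------- FM index
struct FM {
  int n = 0;                      // text length including sentinel
  std::vector<uint8_t> bwt;
  int C[SIGMA + 1] = {0};         // C[c] = # characters < c in text
  std::vector<int> sa;            // full suffix array (sa_stride = 1)
  std::vector<int32_t> ck;        // occ checkpoints, SIGMA per block

  void build(const std::vector<uint8_t>& txt) {
    std::vector<uint8_t> s(txt);
    s.push_back(0);               // sentinel, lexicographically smallest
    n = (int)s.size();
    sa = build_sa(s);
    bwt.resize(n);
    for (int i = 0; i < n; ++i)
      bwt[i] = s[(sa[i] + n - 1) % n];
    int cnt[SIGMA] = {0};
    for (int i = 0; i < n; ++i) cnt[s[i]]++;
    C[0] = 0;
    for (int c = 1; c <= SIGMA; ++c) C[c] = C[c - 1] + cnt[c - 1];
    int nblk = n / CKP + 1;
    ck.assign((size_t)nblk * SIGMA, 0);
    std::vector<int32_t> run(SIGMA, 0);
    for (int i = 0; i < n; ++i) {
      if (i % CKP == 0)
        for (int c = 0; c < SIGMA; ++c) ck[(size_t)(i / CKP) * SIGMA + c] = run[c];
      run[bwt[i]]++;
    }
    if (n % CKP == 0)  // rank(c, n) reads the block-boundary checkpoint
      for (int c = 0; c < SIGMA; ++c) ck[(size_t)(n / CKP) * SIGMA + c] = run[c];
  }

  // occurrences of c in bwt[0..i)
  inline int rank(int c, int i) const {
    int blk = i / CKP;
    int r = ck[(size_t)blk * SIGMA + c];
    for (int j = blk * CKP; j < i; ++j)
      if (bwt[j] == c) ++r;
    return r;
  }

  // backward extension: interval of P -> interval of c.P
  inline void extend(int c, int lo, int hi, int& nlo, int& nhi) const {
    nlo = C[c] + rank(c, lo);
    nhi = C[c] + rank(c, hi);
  }
};

struct FMPair {
  std::string seq;             // uppercase over ACGTN
  std::vector<uint8_t> code;
  int L = 0;
  FM bwd;                      // index of S      (backward search in S)
  FM fwd;                      // index of rev(S) (forward search in S)
};

typedef XPtr<FMPair> PairPtr;

// [[Rcpp::export]]
SEXP fm_build_pair_cpp(std::string seq) {
  if (seq.empty()) stop("reference sequence is empty");
  FMPair* p = new FMPair();
  p->seq = seq;
  p->L = (int)seq.size();
  p->code.resize(p->L);
  for (int i = 0; i < p->L; ++i) {
    int c = code_of(seq[i]);
    if (c < 0) { delete p; stop("invalid character in sequence at position %d", i + 1); }
    p->code[i] = (uint8_t)c;
  }
  p->bwd.build(p->code);
  std::vector<uint8_t> rc(p->code.rbegin(), p->code.rend());
  p->fwd.build(rc);
  return PairPtr(p, true);
}

// [[Rcpp::export]]
int fm_text_length_cpp(SEXP xp) { return PairPtr(xp)->L; }

// [[Rcpp::export]]
std::string fm_bwt_cpp(SEXP xp, bool forward) {
  PairPtr p(xp);
  const FM& f = forward ? p->fwd : p->bwd;
  static const char LET[SIGMA + 1] = "$ACGNT";
  std::string out(f.n, '$');
  for (int i = 0; i < f.n; ++i) out[i] = LET[f.bwt[i]];
  return out;
}

// Backward-search an entire pattern in one index; empty interval on miss.
static void search_pattern(const FM& f, const std::string& pat, int& lo, int& hi) {
  lo = 0; hi = f.n;
  for (int i = (int)pat.size() - 1; i >= 0; --i) {
    int c = code_of(pat[i]);
    if (c <= 0 || c == 4) { lo = hi = 0; return; }  // N or invalid never matches
    f.extend(c, lo, hi, lo, hi);
    if (lo >= hi) { lo = hi = 0; return; }
  }
}

// [[Rcpp::export]]
IntegerVector fm_extend_backward_cpp(SEXP xp, int lo, int hi, std::string ch,
                                     bool forward) {
  PairPtr p(xp);
  const FM& f = forward ? p->fwd : p->bwd;
  if (lo < 0 || hi > f.n || lo > hi) stop("invalid suffix-array interval");
  int c = ch.size() == 1 ? code_of(ch[0]) : -1;
  if (c <= 0 || c == 4) return IntegerVector::create(0, 0);  // N: empty, no error
  int nlo, nhi;
  f.extend(c, lo, hi, nlo, nhi);
  if (nlo >= nhi) { nlo = nhi = 0; }
  return IntegerVector::create(nlo, nhi);
}

// [[Rcpp::export]]
IntegerVector fm_full_interval_cpp(SEXP xp, bool forward) {
  PairPtr p(xp);
  const FM& f = forward ? p->fwd : p->bwd;
  return IntegerVector::create(0, f.n);
}

// [[Rcpp::export]]
int fm_count_cpp(SEXP xp, std::string pattern, bool forward) {
  PairPtr p(xp);
  const FM& f = forward ? p->fwd : p->bwd;
  if (pattern.empty()) return f.n;
  int lo, hi;
  search_pattern(f, pattern, lo, hi);
  return hi - lo;
}

// Ascending 0-based text positions for an interval, capped.
static std::vector<int> interval_positions(const FM& f, int lo, int hi, int cap) {
  std::vector<int> pos;
  for (int i = lo; i < hi; ++i) pos.push_back(f.sa[i]);
  std::sort(pos.begin(), pos.end());
  if ((int)pos.size() > cap) pos.resize(cap);
  return pos;
}

// [[Rcpp::export]]
IntegerVector fm_locate_cpp(SEXP xp, std::string pattern, int cap) {
  PairPtr p(xp);
  if (cap < 1) stop("cap must be >= 1");
  int lo, hi;
  search_pattern(p->bwd, pattern, lo, hi);
  std::vector<int> pos = interval_positions(p->bwd, lo, hi, cap);
  return wrap(pos);
}

// Longest l such that r[p-l..p-1] (1-based) occurs in S, with the 0-based
// genome END positions of that longest string.  p may be m+1 (suffix case).
static void max_back(const FMPair& P, const std::string& r, int p, int max_hits,
                     int& len, std::vector<int>& ends) {
  len = 0;
  ends.clear();
  int lo = 0, hi = P.bwd.n, blo = 0, bhi = 0;
  for (int l = 1; l <= p - 1; ++l) {
    int c = code_of(r[p - 1 - l]);
    if (c <= 0 || c == 4) break;
    int nlo, nhi;
    P.bwd.extend(c, lo, hi, nlo, nhi);
    if (nlo >= nhi) break;
    lo = nlo; hi = nhi; len = l; blo = lo; bhi = hi;
  }
  if (len > 0) {
    std::vector<int> starts = interval_positions(P.bwd, blo, bhi, max_hits);
    for (int s : starts) ends.push_back(s + len - 1);
  }
}

// Longest l such that r[p..p+l-1] occurs in S, with 0-based genome START
// positions; realized by backward search in the index of rev(S).
static void max_fwd(const FMPair& P, const std::string& r, int p, int max_hits,
                    int& len, std::vector<int>& starts) {
  len = 0;
  starts.clear();
  const int m = (int)r.size();
  int lo = 0, hi = P.fwd.n, blo = 0, bhi = 0;
  for (int l = 1; p - 1 + l <= m; ++l) {
    int c = code_of(r[p - 2 + l]);
    if (c <= 0 || c == 4) break;
    int nlo, nhi;
    P.fwd.extend(c, lo, hi, nlo, nhi);
    if (nlo >= nhi) break;
    lo = nlo; hi = nhi; len = l; blo = lo; bhi = hi;
  }
  if (len > 0) {
    std::vector<int> rp = interval_positions(P.fwd, blo, bhi, max_hits);
    for (int q : rp) starts.push_back(P.L - q - len);
    std::sort(starts.begin(), starts.end());
    if ((int)starts.size() > max_hits) starts.resize(max_hits);
  }
}

// [[Rcpp::export]]
List max_match_cpp(SEXP xp, std::string read, int p, bool backward, int max_hits) {
  PairPtr P(xp);
  int m = (int)read.size();
  if (p < 1 || p > m) stop("position p out of range [1, read length]");
  int len;
  std::vector<int> occ;
  if (backward) max_back(*P, read, p, max_hits, len, occ);
  else          max_fwd(*P, read, p, max_hits, len, occ);
  return List::create(_["length"] = len, _["positions"] = wrap(occ));
}

// ------------------------------------------------------------------ seeding
struct Seed {
  bool wrapped;
  int ri, rj;       // 1-based read interval covered (non-wrapped)
  int gstart, len;  // 0-based genome start, total matched length
  int len_f, len_b, q_b_end;  // wrapped-seed geometry
};

static void common_substrings_core(const FMPair& P, const std::string& r, int p,
                                   int W, int max_hits, std::vector<Seed>& out) {
  int len_b, len_f;
  std::vector<int> bends, fstarts;
  max_back(P, r, p, max_hits, len_b, bends);
  max_fwd(P, r, p, max_hits, len_f, fstarts);
  if (len_b > 0 && len_f > 0) {
    if (len_b + len_f < W) return;
    std::vector<int> se(bends);
    std::sort(se.begin(), se.end());
    for (int q : fstarts) {
      if (std::binary_search(se.begin(), se.end(), q - 1)) {
        Seed s{false, p - len_b, p + len_f - 1, q - len_b, len_b + len_f, 0, 0, 0};
        out.push_back(s);
      }
    }
  } else if (len_b == 0 && len_f >= W) {
    for (int q : fstarts)
      out.push_back(Seed{false, p, p + len_f - 1, q, len_f, 0, 0, 0});
  } else if (len_f == 0 && len_b >= W) {
    for (int e : bends)
      out.push_back(Seed{false, p - len_b, p - 1, e - len_b + 1, len_b, 0, 0, 0});
  }
}

static void wraparound_core(const FMPair& P, const std::string& r, int W, int t,
                            int max_hits, std::vector<Seed>& out) {
  const int m = (int)r.size();
  int len_f, len_b;
  std::vector<int> fstarts, bends;
  max_fwd(P, r, 1, max_hits, len_f, fstarts);        // prefix of r
  max_back(P, r, m + 1, max_hits, len_b, bends);     // suffix of r
  if (len_f == m) {  // whole read matches exactly
    for (int q : fstarts)
      out.push_back(Seed{false, 1, m, q, m, 0, 0, 0});
    return;
  }
  if (len_f >= 1 && len_b >= 1 && len_f + len_b >= W && len_f + len_b <= m) {
    for (int qf : fstarts) {
      for (int be : bends) {
        int span = be - qf + 1;
        if (std::abs(span - m) <= t && be - len_b + 1 >= qf + len_f)
          out.push_back(Seed{true, 1, m, qf, len_f + len_b, len_f, len_b, be});
      }
    }
  }
  if (len_f >= W)
    for (int q : fstarts)
      out.push_back(Seed{false, 1, len_f, q, len_f, 0, 0, 0});
  if (len_b >= W)
    for (int e : bends)
      out.push_back(Seed{false, m - len_b + 1, m, e - len_b + 1, len_b, 0, 0, 0});
}

static List seeds_to_list(const std::vector<Seed>& seeds) {
  int n = (int)seeds.size();
  IntegerVector ri(n), rj(n), gs(n), len(n), lf(n), lb(n), qbe(n);
  LogicalVector wr(n);
  for (int i = 0; i < n; ++i) {
    const Seed& s = seeds[i];
    ri[i] = s.ri; rj[i] = s.rj; gs[i] = s.gstart; len[i] = s.len;
    wr[i] = s.wrapped; lf[i] = s.len_f; lb[i] = s.len_b; qbe[i] = s.q_b_end;
  }
  return List::create(_["read_i"] = ri, _["read_j"] = rj,
                      _["genome_start"] = gs, _["length"] = len,
                      _["wrapped"] = wr, _["len_f"] = lf, _["len_b"] = lb,
                      _["q_b_end"] = qbe);
}

// [[Rcpp::export]]
List common_substrings_cpp(SEXP xp, std::string read, int p, int W, int max_hits) {
  PairPtr P(xp);
  int m = (int)read.size();
  if (p < 2 || p > m) stop("position p out of range [2, read length]");
  std::vector<Seed> seeds;
  common_substrings_core(*P, read, p, W, max_hits, seeds);
  return seeds_to_list(seeds);
}

// [[Rcpp::export]]
List wraparound_seeds_cpp(SEXP xp, std::string read, int W, int t, int max_hits) {
  PairPtr P(xp);
  std::vector<Seed> seeds;
  wraparound_core(*P, read, W, t, max_hits, seeds);
  return seeds_to_list(seeds);
}

// -------------------------------------------------------------- edit distance
// [[Rcpp::export]]
int full_edit_cpp(std::string x, std::string y) {
  const int nx = (int)x.size(), ny = (int)y.size();
  std::vector<int> prev(ny + 1), cur(ny + 1);
  for (int j = 0; j <= ny; ++j) prev[j] = j;
  for (int i = 1; i <= nx; ++i) {
    cur[0] = i;
    for (int j = 1; j <= ny; ++j) {
      int sub = prev[j - 1] + (x[i - 1] == y[j - 1] && x[i - 1] != 'N' ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[ny];
}

// Banded bound: value == true distance when <= t, else t+1 with exceeded flag.
// Early exit as soon as every cell of the active band exceeds t.
// max_band_offset instruments the largest |i-j| ever evaluated.
static int bound_edit_core(const std::string& x, const std::string& y, int t,
                           int* max_off) {
  const int nx = (int)x.size(), ny = (int)y.size();
  if (max_off) *max_off = 0;
  if (std::abs(nx - ny) > t) return t + 1;
  if (ny == 0) return nx;  // band check above guarantees nx <= t
  const int INF = t + 1000;
  std::vector<int> prev(ny + 1, INF), cur(ny + 1, INF);
  for (int j = 0; j <= std::min(ny, t); ++j) prev[j] = j;
  if (max_off) *max_off = std::min(ny, t);
  if (nx == 0) return ny <= t ? ny : t + 1;
  for (int i = 1; i <= nx; ++i) {
    int lo = std::max(1, i - t), hi = std::min(ny, i + t);
    if (lo > hi) return t + 1;
    for (int j = lo - 1; j <= hi; ++j) cur[j] = INF;
    if (i <= t) cur[0] = i;
    int rowmin = cur[0] <= t && i <= t ? cur[0] : INF;
    if (i > t) rowmin = INF;
    for (int j = lo; j <= hi; ++j) {
      int sub = prev[j - 1] + (x[i - 1] == y[j - 1] && x[i - 1] != 'N' ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      int v = std::min(sub, std::min(del, ins));
      cur[j] = v;
      if (v < rowmin) rowmin = v;
      if (max_off && std::abs(i - j) > *max_off) *max_off = std::abs(i - j);
    }
    if (i <= t && cur[0] < rowmin) rowmin = cur[0];
    if (rowmin > t) return t + 1;
    std::swap(prev, cur);
  }
  return prev[ny] <= t ? prev[ny] : t + 1;
}

// Literal textbook transliteration of the published pruned recurrence with
// zero-initialized first row/column (study option; not used by the aligner).
static int bound_edit_literal(const std::string& x, const std::string& y, int t) {
  const int nx = (int)x.size(), ny = (int)y.size();
  std::vector<int> prev(ny + 1, 0), cur(ny + 1, 0);
  for (int i = 1; i <= nx; ++i) {
    cur[0] = 0;
    bool all_over = true;
    for (int j = 1; j <= ny; ++j) {
      int sub = prev[j - 1] + (x[i - 1] == y[j - 1] && x[i - 1] != 'N' ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
      if (cur[j] <= t) all_over = false;
    }
    if (ny > 0 && all_over) return t + 1;
    std::swap(prev, cur);
  }
  return prev[ny];
}

// [[Rcpp::export]]
List bound_edit_cpp(std::string x, std::string y, int t, bool literal_init) {
  if (t < 0) stop("t must be >= 0");
  int max_off = 0;
  int v = literal_init ? bound_edit_literal(x, y, t)
                       : bound_edit_core(x, y, t, &max_off);
  bool exceeded = v > t;
  if (!literal_init && exceeded) v = t + 1;
  return List::create(_["value"] = v, _["exceeded"] = exceeded,
                      _["max_band_offset"] = max_off);
}

// ------------------------------------------------------------------- aligner
struct Cand {
  int gstart, gend, dist, dl, dr;
  int strand;  // 0 = '+', 1 = '-'
};

static bool extend_seed_core(const FMPair& P, const Seed& s, const std::string& r,
                             int t, Cand& out) {
  const int m = (int)r.size();
  const std::string& S = P.seq;
  if (s.wrapped) {
    int gap_from = s.gstart + s.len_f;
    int gap_to = s.q_b_end - s.len_b + 1;      // exclusive..inclusive boundary
    if (gap_to < gap_from) return false;
    std::string mid = r.substr(s.len_f, m - s.len_b - s.len_f);
    std::string gap = S.substr(gap_from, gap_to - gap_from);
    int d = bound_edit_core(mid, gap, t, nullptr);
    if (d > t) return false;
    out = Cand{s.gstart, s.q_b_end + 1, d, d, 0, 0};
    return true;
  }
  int lflank = s.ri - 1;
  int ls = s.gstart - lflank;
  int from = std::max(ls, 0);
  std::string sL = S.substr(from, s.gstart - from);
  std::string rpre = r.substr(0, s.ri - 1);
  int dl = bound_edit_core(rpre, sL, t, nullptr);
  if (dl > t) return false;
  int rs = s.gstart + s.len;
  int rlen = m - s.rj;
  int to = std::min(rs + rlen, P.L);
  std::string sR = S.substr(rs, to - rs);
  std::string rsuf = r.substr(s.rj, m - s.rj);
  int dr = bound_edit_core(rsuf, sR, t - dl, nullptr);
  if (dl + dr > t) return false;
  out = Cand{from, to, dl + dr, dl, dr, 0};
  return true;
}

// [[Rcpp::export]]
List extend_seed_cpp(SEXP xp, std::string read, int read_i, int read_j,
                     int genome_start, int len, bool wrapped, int len_f,
                     int len_b, int q_b_end, int t) {
  PairPtr P(xp);
  Seed s{wrapped, read_i, read_j, genome_start, len, len_f, len_b, q_b_end};
  Cand c;
  bool ok = extend_seed_core(*P, s, read, t, c);
  if (!ok) return List::create(_["accepted"] = false);
  return List::create(_["accepted"] = true, _["genome_start"] = c.gstart,
                      _["genome_end"] = c.gend, _["dist"] = c.dist,
                      _["dist_left"] = c.dl, _["dist_right"] = c.dr);
}

static uint64_t splitmix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// Deterministic per-read RNG stream: xorshift-style generator seeded by
// mixing (base_seed, ordinal); independent of batch partitioning.
struct Rng {
  uint64_t state;
  Rng(uint32_t base, uint32_t ordinal) {
    state = splitmix64(((uint64_t)base << 32) ^ (uint64_t)ordinal);
    if (state == 0) state = 0x106689d45497fdb5ULL;
  }
  uint64_t next() {
    uint64_t x = state;
    x ^= x << 13; x ^= x >> 7; x ^= x << 17;
    state = x;
    return x;
  }
  int uniform_int(int lo, int hi) {  // inclusive both ends
    return lo + (int)(next() % (uint64_t)(hi - lo + 1));
  }
};

enum Status { ALIGNED = 0, AMBIGUOUS = 1, UNALIGNED = 2 };

static void align_read_core(const FMPair& P, const std::string& read, int t,
                            int W, int A, int max_hits, Rng& rng, int& status,
                            int& attempts, std::vector<Cand>& cands) {
  const int m = (int)read.size();
  const std::string rc = revcomp(read);
  cands.clear();
  status = UNALIGNED;
  attempts = 0;
  for (int att = 1; att <= A; ++att) {
    attempts = att;
    int p = att == 1 ? 1 : rng.uniform_int(1, m);
    std::vector<Cand> C;
    for (int strand = 0; strand <= 1; ++strand) {
      const std::string& rs = strand ? rc : read;
      std::vector<Seed> seeds;
      if (p == 1) wraparound_core(P, rs, W, t, max_hits, seeds);
      else        common_substrings_core(P, rs, p, W, max_hits, seeds);
      for (const Seed& s : seeds) {
        Cand c;
        if (extend_seed_core(P, s, rs, t, c)) {
          c.strand = strand;
          C.push_back(c);
        }
      }
    }
    if (C.empty()) continue;
    // collapse duplicates (same genome_start and strand), keep min dist
    std::sort(C.begin(), C.end(), [](const Cand& a, const Cand& b) {
      if (a.gstart != b.gstart) return a.gstart < b.gstart;
      if (a.strand != b.strand) return a.strand < b.strand;
      return a.dist < b.dist;
    });
    std::vector<Cand> U;
    for (const Cand& c : C) {
      if (!U.empty() && U.back().gstart == c.gstart && U.back().strand == c.strand)
        continue;
      U.push_back(c);
    }
    if ((int)U.size() > 2) { status = AMBIGUOUS; return; }
    // primary ordering: lower dist, then leftmost start, then '+' strand
    std::sort(U.begin(), U.end(), [](const Cand& a, const Cand& b) {
      if (a.dist != b.dist) return a.dist < b.dist;
      if (a.gstart != b.gstart) return a.gstart < b.gstart;
      return a.strand < b.strand;
    });
    cands = U;
    status = ALIGNED;
    return;
  }
}

static List result_to_list(int status, int attempts, const std::vector<Cand>& cs) {
  int n = (int)cs.size();
  IntegerVector gs(n), ge(n), d(n), dl(n), dr(n);
  CharacterVector st(n);
  for (int i = 0; i < n; ++i) {
    gs[i] = cs[i].gstart; ge[i] = cs[i].gend; d[i] = cs[i].dist;
    dl[i] = cs[i].dl; dr[i] = cs[i].dr;
    st[i] = cs[i].strand ? "-" : "+";
  }
  return List::create(
      _["status"] = status, _["attempts_used"] = attempts,
      _["candidates"] = DataFrame::create(
          _["genome_start"] = gs, _["genome_end"] = ge, _["dist"] = d,
          _["dist_left"] = dl, _["dist_right"] = dr, _["strand"] = st,
          _["stringsAsFactors"] = false));
}

// [[Rcpp::export]]
List align_read_cpp(SEXP xp, std::string read, int t, int W, int A, int max_hits,
                    int base_seed, int ordinal) {
  PairPtr P(xp);
  if (read.empty()) stop("empty read");
  Rng rng((uint32_t)base_seed, (uint32_t)ordinal);
  int status, attempts;
  std::vector<Cand> cands;
  align_read_core(*P, read, t, W, A, max_hits, rng, status, attempts, cands);
  return result_to_list(status, attempts, cands);
}

// [[Rcpp::export]]
List align_batch_cpp(SEXP xp, CharacterVector reads, int t, int W, int A,
                     int max_hits, int base_seed, IntegerVector ordinals) {
  PairPtr P(xp);
  const int n = reads.size();
  IntegerVector status(n), attempts(n), pos(n), endp(n), dist(n), ncand(n),
      pos2(n), dist2(n);
  CharacterVector strand(n), strand2(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    Rng rng((uint32_t)base_seed, (uint32_t)ordinals[i]);
    int st, at;
    std::vector<Cand> cs;
    align_read_core(*P, rd, t, W, A, max_hits, rng, st, at, cs);
    status[i] = st; attempts[i] = at;
    ncand[i] = (int)cs.size();
    if (st == ALIGNED) {
      pos[i] = cs[0].gstart; endp[i] = cs[0].gend; dist[i] = cs[0].dist;
      strand[i] = cs[0].strand ? "-" : "+";
      if (cs.size() > 1) {
        pos2[i] = cs[1].gstart; dist2[i] = cs[1].dist;
        strand2[i] = cs[1].strand ? "-" : "+";
      } else {
        pos2[i] = NA_INTEGER; dist2[i] = NA_INTEGER; strand2[i] = NA_STRING;
      }
    } else {
      pos[i] = NA_INTEGER; endp[i] = NA_INTEGER; dist[i] = NA_INTEGER;
      strand[i] = NA_STRING;
      pos2[i] = NA_INTEGER; dist2[i] = NA_INTEGER; strand2[i] = NA_STRING;
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["status"] = status, _["attempts_used"] = attempts,
                      _["genome_start"] = pos, _["genome_end"] = endp,
                      _["dist"] = dist, _["strand"] = strand,
                      _["n_candidates"] = ncand, _["genome_start2"] = pos2,
                      _["dist2"] = dist2, _["strand2"] = strand2);
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) { return revcomp(s); }

// ------------------------------------------------------- block-model simulation
// d distinct cut points (differences) split a length-m read into d+1 blocks,
// each block ending at its difference; a uniform position p selects the block
// it lands in.  Returns the Monte-Carlo mean of the sampled block's length.
// [[Rcpp::export]]
double block_model_mean_cpp(int m, int d, int n_trials, int seed) {
  if (m < 1 || d < 0 || d > m) stop("need 0 <= d <= m, m >= 1");
  if (d == 0) return (double)m;
  Rng rng((uint32_t)seed, 0xb10c0000u + (uint32_t)d);
  std::vector<int> cuts(d);
  std::vector<char> used(m + 1);
  double tot = 0.0;
  for (int tr = 0; tr < n_trials; ++tr) {
    std::fill(used.begin(), used.end(), 0);
    int got = 0;
    while (got < d) {
      int v = rng.uniform_int(1, m);
      if (!used[v]) { used[v] = 1; cuts[got++] = v; }
    }
    std::sort(cuts.begin(), cuts.end());
    int p = rng.uniform_int(1, m);
    int idx = 0;
    while (idx < d && cuts[idx] < p) ++idx;
    int lo = idx == 0 ? 0 : cuts[idx - 1];
    int hi = idx == d ? m : cuts[idx];
    tot += hi - lo;
  }
  return tot / n_trials;
}

// -------------------------------------------------------------- repeat density
// D(S|k): fraction of valid k-mer windows whose k-mer occurs >= 2 times.
// Windows containing N are excluded from numerator and denominator.
// [[Rcpp::export]]
NumericVector repeat_density_cpp(std::string seq, IntegerVector ks) {
  const int L = (int)seq.size();
  std::vector<uint8_t> code(L + 1);
  for (int i = 0; i < L; ++i) {
    int c = code_of(seq[i]);
    if (c < 0) stop("invalid character in sequence");
    code[i] = (uint8_t)c;
  }
  code[L] = 0;  // sentinel
  std::vector<int> sa = build_sa(code);
  std::vector<int> lcp = build_lcp(code, sa);
  std::vector<int> rank_(L + 1);
  for (int i = 0; i <= L; ++i) rank_[sa[i]] = i;
  // nn[i] = first position >= i holding an N (or L if none)
  std::vector<int> nn(L + 1, L);
  for (int i = L - 1; i >= 0; --i)
    nn[i] = (seq[i] == 'N') ? i : nn[i + 1];
  NumericVector out(ks.size());
  for (int kk = 0; kk < ks.size(); ++kk) {
    int k = ks[kk];
    if (k < 1 || k > L) stop("k must be in [1, genome length]");
    long denom = 0, num = 0;
    for (int i = 0; i + k <= L; ++i) {
      if (nn[i] < i + k) continue;  // window spans an N
      ++denom;
      int r = rank_[i];
      bool rep = (lcp[r] >= k) || (r + 1 <= L && lcp[r + 1] >= k);
      if (rep) ++num;
    }
    out[kk] = denom > 0 ? (double)num / (double)denom : NA_REAL;
  }
  return out;
}
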