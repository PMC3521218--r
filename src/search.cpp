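#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_set>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3, leftmost base most significant.
// Codes fit a uint64_t for l <= 32; exactness through R doubles caps l at 26.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BASES[5] = "ACGT";

static uint64_t encode_string(const std::string& x) {
  uint64_t code = 0;
  for (char c : x) {
    int b = base_code(c);
    if (b < 0) stop("invalid alphabet: character '%s' is not in {A,C,G,T}",
                    std::string(1, c).c_str());
    code = (code << 2) | (uint64_t)b;
  }
  return code;
}

static std::string decode_code(uint64_t code, int l) {
  std::string out(l, 'A');
  for (int i = l - 1; i >= 0; --i) {
    out[i] = BASES[code & 3ULL];
    code >>= 2;
  }
  return out;
}

// mismatch count between two 2-bit packed l-mers
static inline int mismatches(uint64_t a, uint64_t b) {
  uint64_t z = a ^ b;
  z = (z | (z >> 1)) & 0x5555555555555555ULL;
  return __builtin_popcountll(z);
}

// all l-length window codes of a sequence
static std::vector<uint64_t> window_codes(const std::string& s, int l) {
  int m = (int)s.size() - l + 1;
  if (m < 1) stop("sequence of length %d is shorter than l = %d", (int)s.size(), l);
  std::vector<uint64_t> w((size_t)m);
  uint64_t mask = (l == 32) ? ~0ULL : ((1ULL << (2 * l)) - 1ULL);
  uint64_t cur = 0;
  for (int i = 0; i < (int)s.size(); ++i) {
    int b = base_code(s[i]);
    if (b < 0) stop("invalid alphabet: character '%s' at position %d",
                    std::string(1, s[i]).c_str(), i + 1);
    cur = ((cur << 2) | (uint64_t)b) & mask;
    if (i >= l - 1) w[(size_t)(i - l + 1)] = cur;
  }
  return w;
}

// Enumerate every code within Hamming distance d of y exactly once:
// mismatch positions are chosen strictly left-to-right and each receives a
// base different from y's, so each member of the ball has a unique path.
template <typename F>
static void enum_ball(uint64_t y, int l, int d, int used, int from_pos, F&& f) {
  f(y);
  if (used == d) return;
  for (int p = from_pos; p < l; ++p) {
    int shift = 2 * (l - 1 - p);
    uint64_t cur = (y >> shift) & 3ULL;
    uint64_t cleared = y & ~(3ULL << shift);
    for (uint64_t nb = 0; nb < 4; ++nb) {
      if (nb == cur) continue;
      enum_ball(cleared | (nb << shift), l, d, used + 1, p + 1, f);
    }
  }
}

// presence bitmap over the 4^l code space
struct Bitset {
  std::vector<uint64_t> bits;
  void init(uint64_t n) { bits.assign((size_t)((n + 63) / 64), 0ULL); }
  bool test(uint64_t i) const { return (bits[i >> 6] >> (i & 63)) & 1ULL; }
  void set(uint64_t i) { bits[i >> 6] |= (1ULL << (i & 63)); }
};

// dedup structure: bitmap when 4^l fits the budget, hash set otherwise
struct DedupSet {
  bool use_bitmap = false;
  Bitset bm;
  std::unordered_set<uint64_t> hs;
  void init(int l, int bitmap_max_l) {
    use_bitmap = (l <= bitmap_max_l);
    if (use_bitmap) bm.init(1ULL << (2 * l));
  }
  bool test_and_set(uint64_t x) {
    if (use_bitmap) {
      if (bm.test(x)) return true;
      bm.set(x);
      return false;
    }
    return !hs.insert(x).second;
  }
  bool contains(uint64_t x) const {
    if (use_bitmap) return bm.test(x);
    return hs.count(x) > 0;
  }
};

// does x have a window within distance d in every sequence wins[from..]?
static inline bool has_hit(uint64_t x, const uint64_t* w, size_t m, int d) {
  size_t j = 0;
  // unrolled by 4: one branch per block keeps the pipeline full on the
  // common all-miss path
  for (; j + 4 <= m; j += 4) {
    int m0 = mismatches(x, w[j]);
    int m1 = mismatches(x, w[j + 1]);
    int m2 = mismatches(x, w[j + 2]);
    int m3 = mismatches(x, w[j + 3]);
    int best = std::min(std::min(m0, m1), std::min(m2, m3));
    if (best <= d) return true;
  }
  for (; j < m; ++j)
    if (mismatches(x, w[j]) <= d) return true;
  return false;
}

static inline bool hits_all(uint64_t x, const std::vector<std::vector<uint64_t>>& wins,
                            size_t from, int d) {
  for (size_t s = from; s < wins.size(); ++s) {
    if (!has_hit(x, wins[s].data(), wins[s].size(), d)) return false;
  }
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_encode(CharacterVector lmers) {
  NumericVector out(lmers.size());
  for (R_xlen_t i = 0; i < lmers.size(); ++i)
    out[i] = (double)encode_string(as<std::string>(lmers[i]));
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode(NumericVector codes, int l) {
  CharacterVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    out[i] = decode_code((uint64_t)codes[i], l);
  return out;
}

// [[Rcpp::export]]
int cpp_hamming(std::string x, std::string y) {
  if (x.size() != y.size()) stop("length mismatch: |x| = %d, |y| = %d",
                                 (int)x.size(), (int)y.size());
  return mismatches(encode_string(x), encode_string(y));
}

// [[Rcpp::export]]
int cpp_min_distance(std::string x, std::string s) {
  int l = (int)x.size();
  uint64_t xc = encode_string(x);
  std::vector<uint64_t> w = window_codes(s, l);
  int best = l + 1;
  for (uint64_t v : w) {
    int m = mismatches(xc, v);
    if (m < best) best = m;
    if (best == 0) break;
  }
  return best;
}

// first 0-based window start achieving the minimum distance, per sequence
// [[Rcpp::export]]
List cpp_best_positions(std::string x, CharacterVector seqs) {
  int l = (int)x.size();
  uint64_t xc = encode_string(x);
  IntegerVector pos(seqs.size());
  IntegerVector dist(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::vector<uint64_t> w = window_codes(as<std::string>(seqs[i]), l);
    int best = l + 1, at = 0;
    for (size_t j = 0; j < w.size(); ++j) {
      int m = mismatches(xc, w[j]);
      if (m < best) { best = m; at = (int)j; if (best == 0) break; }
    }
    pos[i] = at;
    dist[i] = best;
  }
  return List::create(_["position"] = pos, _["distance"] = dist);
}

// [[Rcpp::export]]
CharacterVector cpp_neighborhood(std::string x, int d) {
  int l = (int)x.size();
  if (d < 0 || d > l) stop("d must be in [0, l]");
  uint64_t xc = encode_string(x);
  std::vector<uint64_t> out;
  enum_ball(xc, l, d, 0, 0, [&](uint64_t v) { out.push_back(v); });
  std::sort(out.begin(), out.end());
  CharacterVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = decode_code(out[i], l);
  return res;
}

// [[Rcpp::export]]
NumericVector cpp_brute_force(CharacterVector seqs, int l, int d) {
  std::vector<std::vector<uint64_t>> wins(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    wins[(size_t)i] = window_codes(as<std::string>(seqs[i]), l);
  uint64_t total = 1ULL << (2 * l);
  std::vector<uint64_t> out;
  for (uint64_t x = 0; x < total; ++x) {
    if ((x & 0xFFFFFULL) == 0) Rcpp::checkUserInterrupt();
    if (hits_all(x, wins, 0, d)) out.push_back(x);
  }
  return NumericVector(out.begin(), out.end());
}

// Candidate stage: for every l-mer y of s1 with start index in [from, to),
// enumerate the ball B_d(y) and keep x iff every sequence of the subset has a
// window within distance d of x.  dedup_seen = true is the optimized engine
// (an l-mer is tested at most once across all balls); false is the reference
// engine that re-tests duplicates and deduplicates output only.
// [[Rcpp::export]]
NumericVector cpp_candidate_search(CharacterVector seqs, int l, int d,
                                   int from, int to,
                                   bool dedup_seen, int bitmap_max_l) {
  if (seqs.size() < 1) stop("need at least one sequence");
  std::vector<std::vector<uint64_t>> wins(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    wins[(size_t)i] = window_codes(as<std::string>(seqs[i]), l);
  int m = (int)wins[0].size();
  if (from < 0 || to > m || from > to) stop("window range [%d,%d) outside [0,%d)", from, to, m);

  DedupSet seen, cand;
  if (dedup_seen) seen.init(l, bitmap_max_l);
  cand.init(l, bitmap_max_l);
  std::vector<uint64_t> out;

  for (int i = from; i < to; ++i) {
    Rcpp::checkUserInterrupt();
    enum_ball(wins[0][i], l, d, 0, 0, [&](uint64_t x) {
      if (dedup_seen) {
        if (seen.test_and_set(x)) return;
      } else if (cand.contains(x)) {
        return;
      }
      // x is within d of a window of s1 by construction; check the rest
      if (hits_all(x, wins, 1, d)) {
        if (!cand.test_and_set(x)) out.push_back(x);
      }
    });
  }
  std::sort(out.begin(), out.end());
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
LogicalVector cpp_validate(NumericVector codes, CharacterVector seqs, int l, int d) {
  std::vector<std::vector<uint64_t>> wins(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    wins[(size_t)i] = window_codes(as<std::string>(seqs[i]), l);
  LogicalVector keep(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    keep[i] = hits_all((uint64_t)codes[i], wins, 0, d);
  }
  return keep;
}

// Incremental duplicate-free merge: append each list in order, discarding
// elements already present (lookup-table dedup for small l, hash otherwise).
// [[Rcpp::export]]
NumericVector cpp_merge_lists(List lists, int l, int bitmap_max_l) {
  DedupSet seen;
  seen.init(l, bitmap_max_l);
  std::vector<uint64_t> out;
  for (R_xlen_t j = 0; j < lists.size(); ++j) {
    NumericVector lj = lists[j];
    for (R_xlen_t i = 0; i < lj.size(); ++i) {
      uint64_t x = (uint64_t)lj[i];
      if (!seen.test_and_set(x)) out.push_back(x);
    }
  }
  std::sort(out.begin(), out.end());
  return NumericVector(out.begin(), out.end());
}
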