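// Bit-parallel approximate matcher for junction-spanning read counting.
//
// Semi-global edit distance: minimum number of substitutions/insertions/
// deletions needed to turn the whole pattern into some substring of the
// text. Myers' bit-vector algorithm (O(n) per text for patterns up to 64
// symbols); plain dynamic programming fallback for longer patterns.
// Only A/C/G/T can match; N (or any other symbol) on either side is a
// guaranteed mismatch.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base_index(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static int semiglobal_myers64(const std::string &p, const std::string &t) {
  const int m = static_cast<int>(p.size());
  const int n = static_cast<int>(t.size());
  uint64_t peq[4] = {0, 0, 0, 0};
  for (int i = 0; i < m; ++i) {
    int b = base_index(p[i]);
    if (b >= 0) peq[b] |= (1ULL << i);
  }
  uint64_t Pv = ~0ULL, Mv = 0;
  const uint64_t high = 1ULL << (m - 1);
  int score = m, best = m;
  for (int j = 0; j < n; ++j) {
    int b = base_index(t[j]);
    uint64_t Eq = (b >= 0) ? peq[b] : 0ULL;
    uint64_t Xv = Eq | Mv;
    uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
    uint64_t Ph = Mv | ~(Xh | Pv);
    uint64_t Mh = Pv & Xh;
    if (Ph & high) ++score; else if (Mh & high) --score;
    Ph <<= 1;   // no carry-in: row 0 is all zeros (free text prefix)
    Mh <<= 1;
    Pv = Mh | ~(Xv | Ph);
    Mv = Ph & Xv;
    if (score < best) best = score;
  }
  return best;
}

static int semiglobal_dp(const std::string &p, const std::string &t) {
  const int m = static_cast<int>(p.size());
  const int n = static_cast<int>(t.size());
  std::vector<int> prev(n + 1, 0), cur(n + 1);
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    int bp = base_index(p[i - 1]);
    for (int j = 1; j <= n; ++j) {
      int bt = base_index(t[j - 1]);
      int v = prev[j - 1] + ((bp >= 0 && bp == bt) ? 0 : 1);
      if (prev[j] + 1 < v) v = prev[j] + 1;
      if (cur[j - 1] + 1 < v) v = cur[j - 1] + 1;
      cur[j] = v;
    }
    prev.swap(cur);
  }
  int best = prev[0];
  for (int j = 1; j <= n; ++j)
    if (prev[j] < best) best = prev[j];
  return best;
}

static inline int semiglobal(const std::string &p, const std::string &t) {
  if (p.empty()) return 0;
  if (t.empty()) return static_cast<int>(p.size());
  if (p.size() <= 64) return semiglobal_myers64(p, t);
  return semiglobal_dp(p, t);
}

// [[Rcpp::export]]
IntegerVector cpp_semiglobal_distance(std::string probe, CharacterVector texts) {
  const int n = texts.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = semiglobal(probe, as<std::string>(texts[i]));
  }
  return out;
}

// Match in either orientation (forward read or its reverse complement,
// both precomputed on the R side); a read matching both still counts once.
// [[Rcpp::export]]
LogicalVector cpp_match_either(std::string probe, CharacterVector fwd,
                               CharacterVector rev, int k) {
  const int n = fwd.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    bool hit = semiglobal(probe, as<std::string>(fwd[i])) <= k;
    if (!hit) hit = semiglobal(probe, as<std::string>(rev[i])) <= k;
    out[i] = hit;
  }
  return out;
}
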