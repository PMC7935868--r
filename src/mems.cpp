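#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// N never matches anything, including itself: identity percentages stay
// well defined on contigs that carry ambiguous bases.
static inline bool chareq(char x, char y) {
  return x == y && x != 'N' && x != 'n';
}

static inline int base2(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

// All maximal exact matches (MEMs) of length >= min_len between a and b,
// forward strand, maxmatch semantics (non-unique matches included).
//
// Every MEM of length >= min_len starts with a k-mer (k <= min_len) whose
// preceding characters differ (or that abuts a sequence start), so MEMs are
// enumerated exactly once by scanning b for start-anchored k-mer matches
// against a hash index of a and extending right to maximality.
// [[Rcpp::export]]
DataFrame find_mems_cpp(std::string a, std::string b, int min_len) {
  const int na = (int) a.size(), nb = (int) b.size();
  std::vector<int> a_out, b_out, l_out;
  int k = min_len < 14 ? min_len : 14;
  if (k < 4) k = 4;
  if (na >= k && nb >= k) {
    std::unordered_map<uint32_t, std::vector<int> > idx;
    idx.reserve((size_t) na * 2);
    const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
    // index a
    {
      uint32_t h = 0; int run = 0;
      for (int i = 0; i < na; ++i) {
        int c = base2(a[(size_t) i]);
        if (c < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint32_t) c) & mask;
        if (++run >= k) idx[h].push_back(i - k + 1);
      }
    }
    // scan b
    uint32_t h = 0; int run = 0;
    for (int j = 0; j < nb; ++j) {
      int c = base2(b[(size_t) j]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t) c) & mask;
      if (++run < k) continue;
      int j0 = j - k + 1;
      std::unordered_map<uint32_t, std::vector<int> >::const_iterator it = idx.find(h);
      if (it == idx.end()) continue;
      const std::vector<int>& pos = it->second;
      for (size_t t = 0; t < pos.size(); ++t) {
        int i0 = pos[t];
        // left-maximal start?
        if (i0 > 0 && j0 > 0 && chareq(a[(size_t) (i0 - 1)], b[(size_t) (j0 - 1)]))
          continue;
        // extend right to maximality
        int i = i0 + k, j2 = j0 + k;
        while (i < na && j2 < nb && chareq(a[(size_t) i], b[(size_t) j2])) { ++i; ++j2; }
        int len = i - i0;
        if (len >= min_len) {
          a_out.push_back(i0); b_out.push_back(j0); l_out.push_back(len);
        }
      }
    }
  }
  return DataFrame::create(_["a_start"] = a_out, _["b_start"] = b_out,
                           _["length"] = l_out);
}

// Exact k-mer seed hits of query against target (forward strand only;
// reverse strand handled by the caller on the reverse complement).
// [[Rcpp::export]]
DataFrame seed_hits_cpp(std::string query, std::string target, int k) {
  const int nq = (int) query.size(), nt = (int) target.size();
  std::vector<int> q_out, t_out;
  if (nq >= k && nt >= k && k >= 4 && k <= 16) {
    const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
    std::unordered_map<uint32_t, std::vector<int> > idx;
    idx.reserve((size_t) nq * 2);
    {
      uint32_t h = 0; int run = 0;
      for (int i = 0; i < nq; ++i) {
        int c = base2(query[(size_t) i]);
        if (c < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint32_t) c) & mask;
        if (++run >= k) idx[h].push_back(i - k + 1);
      }
    }
    uint32_t h = 0; int run = 0;
    for (int j = 0; j < nt; ++j) {
      int c = base2(target[(size_t) j]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t) c) & mask;
      if (++run < k) continue;
      std::unordered_map<uint32_t, std::vector<int> >::const_iterator it = idx.find(h);
      if (it == idx.end()) continue;
      const std::vector<int>& pos = it->second;
      for (size_t t = 0; t < pos.size(); ++t) {
        q_out.push_back(pos[t]); t_out.push_back(j - k + 1);
      }
    }
  }
  return DataFrame::create(_["qpos"] = q_out, _["tpos"] = t_out);
}

// Booth's least-rotation algorithm: 0-based index of the lexicographically
// minimal rotation of s.
// [[Rcpp::export]]
int least_rotation_cpp(std::string s) {
  const int n = (int) s.size();
  if (n == 0) return 0;
  std::string ss = s + s;
  std::vector<int> f(2 * (size_t) n, -1);
  int kk = 0;
  for (int j = 1; j < 2 * n; ++j) {
    char sj = ss[(size_t) j];
    int i = f[(size_t) (j - kk - 1)];
    while (i != -1 && sj != ss[(size_t) (kk + i + 1)]) {
      if (sj < ss[(size_t) (kk + i + 1)]) kk = j - i - 1;
      i = f[(size_t) i];
    }
    if (sj != ss[(size_t) (kk + i + 1)]) {
      if (sj < ss[(size_t) kk]) kk = j;
      f[(size_t) (j - kk)] = -1;
    } else {
      f[(size_t) (j - kk)] = i + 1;
    }
    if (kk + n <= j) break;
  }
  return kk;
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    case 'U': return 'A'; case 'u': return 'a';
    default:  return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  const int n = x.size();
  CharacterVector out(n);
  std::string r;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(x, i));
    int m = (int) LENGTH(STRING_ELT(x, i));
    r.resize((size_t) m);
    for (int j = 0; j < m; ++j) r[(size_t) (m - 1 - j)] = comp(s[j]);
    out[i] = r;
  }
  return out;
}
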