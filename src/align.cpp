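#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <limits>
using namespace Rcpp;

static inline bool chareq(char x, char y) {
  return x == y && x != 'N' && x != 'n';
}

// gap costs more than a mismatch pair gains: adjacent substitutions are
// realized as mismatch columns, not as compensating gap pairs, keeping
// consensus columns positionally stable
static const int MATCH = 2, MISMATCH = -4, GAP = -5;
static const int NEG = std::numeric_limits<int>::min() / 4;

// Banded global (Needleman-Wunsch) alignment of a vs b restricted to
// diagonals d = j - i in [dlo, dhi].  The band must contain the start (0)
// and end (nb - na) diagonals; the R wrapper guarantees this.
// Returns score, matches, columns and (optionally) the aligned strings.
// [[Rcpp::export]]
List nw_band_cpp(std::string a, std::string b, int dlo, int dhi,
                 bool keep_align = false) {
  const int na = (int) a.size(), nb = (int) b.size();
  const int W = dhi - dlo + 1;
  if (W <= 0 || dlo > 0 || dhi < nb - na)
    stop("alignment band does not contain the global path");
  std::vector<int> prev((size_t) W, NEG), cur((size_t) W, NEG);
  // moves: 0 = diag, 1 = up (gap in b), 2 = left (gap in a)
  std::vector<uint8_t> tb((size_t) (na + 1) * (size_t) W, 255);
  for (int j = 0; j <= nb; ++j) {            // row i = 0
    int w = j - dlo;
    if (w < 0 || w >= W) continue;
    prev[(size_t) w] = GAP * j;
    tb[(size_t) w] = (j == 0) ? 254 : 2;
  }
  for (int i = 1; i <= na; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    int jlo = i + dlo, jhi = i + dhi;
    if (jlo < 0) jlo = 0;
    if (jhi > nb) jhi = nb;
    for (int j = jlo; j <= jhi; ++j) {
      int w = j - i - dlo;
      int best = NEG; uint8_t mv = 255;
      if (j > 0) {                            // diag from (i-1, j-1): same w
        int s = prev[(size_t) w];
        if (s > NEG) {
          s += chareq(a[(size_t) (i - 1)], b[(size_t) (j - 1)]) ? MATCH : MISMATCH;
          if (s > best) { best = s; mv = 0; }
        }
      }
      if (w + 1 < W) {                        // up from (i-1, j): w + 1
        int s = prev[(size_t) (w + 1)];
        if (s > NEG && s + GAP > best) { best = s + GAP; mv = 1; }
      }
      if (w - 1 >= 0) {                       // left from (i, j-1): w - 1
        int s = cur[(size_t) (w - 1)];
        if (s > NEG && s + GAP > best) { best = s + GAP; mv = 2; }
      }
      cur[(size_t) w] = best;
      tb[(size_t) i * (size_t) W + (size_t) w] = mv;
    }
    std::swap(prev, cur);
  }
  int wend = nb - na - dlo;
  int score = prev[(size_t) wend];
  // traceback
  long matches = 0, columns = 0;
  std::string aa, ba;
  int i = na, j = nb;
  while (i > 0 || j > 0) {
    uint8_t mv = tb[(size_t) i * (size_t) W + (size_t) (j - i - dlo)];
    if (mv == 0) {
      ++columns;
      if (chareq(a[(size_t) (i - 1)], b[(size_t) (j - 1)])) ++matches;
      if (keep_align) { aa.push_back(a[(size_t) (i - 1)]); ba.push_back(b[(size_t) (j - 1)]); }
      --i; --j;
    } else if (mv == 1) {
      ++columns;
      if (keep_align) { aa.push_back(a[(size_t) (i - 1)]); ba.push_back('-'); }
      --i;
    } else if (mv == 2) {
      ++columns;
      if (keep_align) { aa.push_back('-'); ba.push_back(b[(size_t) (j - 1)]); }
      --j;
    } else {
      stop("corrupt traceback");
    }
  }
  if (keep_align) {
    std::reverse(aa.begin(), aa.end());
    std::reverse(ba.begin(), ba.end());
  }
  List out = List::create(_["score"] = score, _["matches"] = (double) matches,
                          _["columns"] = (double) columns,
                          _["identity"] = columns > 0 ? 100.0 * matches / columns : 0.0);
  if (keep_align) { out["a_aligned"] = aa; out["b_aligned"] = ba; }
  return out;
}

// Banded local (Smith-Waterman) alignment restricted to diagonals
// d = j - i in [dlo, dhi].  Returns the single best local alignment:
// 0-based half-open intervals on a and b, matches and columns.
// [[Rcpp::export]]
List sw_band_cpp(std::string a, std::string b, int dlo, int dhi) {
  const int na = (int) a.size(), nb = (int) b.size();
  int W = dhi - dlo + 1;
  if (W <= 0) stop("empty band");
  std::vector<int> prev((size_t) W, 0), cur((size_t) W, 0);
  std::vector<uint8_t> tb((size_t) (na + 1) * (size_t) W, 3); // 3 = stop
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= na; ++i) {
    std::fill(cur.begin(), cur.end(), 0);
    int jlo = i + dlo, jhi = i + dhi;
    if (jlo < 1) jlo = 1;
    if (jhi > nb) jhi = nb;
    for (int j = jlo; j <= jhi; ++j) {
      int w = j - i - dlo;
      int sc = 0; uint8_t mv = 3;
      {
        // diag: cell (i-1, j-1) is valid iff its diagonal is in band
        int s = (j - i >= dlo && j - i <= dhi) ? prev[(size_t) w] : 0;
        s += chareq(a[(size_t) (i - 1)], b[(size_t) (j - 1)]) ? MATCH : MISMATCH;
        if (s > sc) { sc = s; mv = 0; }
      }
      if (w + 1 < W) {
        int s = prev[(size_t) (w + 1)] + GAP;
        if (s > sc) { sc = s; mv = 1; }
      }
      if (w - 1 >= 0) {
        int s = cur[(size_t) (w - 1)] + GAP;
        if (s > sc) { sc = s; mv = 2; }
      }
      cur[(size_t) w] = sc;
      tb[(size_t) i * (size_t) W + (size_t) w] = mv;
      if (sc > best) { best = sc; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  long matches = 0, columns = 0;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    uint8_t mv = tb[(size_t) i * (size_t) W + (size_t) (j - i - dlo)];
    if (mv == 3) break;
    if (mv == 0) {
      ++columns;
      if (chareq(a[(size_t) (i - 1)], b[(size_t) (j - 1)])) ++matches;
      --i; --j;
    } else if (mv == 1) { ++columns; --i; }
    else { ++columns; --j; }
  }
  return List::create(_["score"] = best,
                      _["a_lo"] = i, _["a_hi"] = bi,
                      _["b_lo"] = j, _["b_hi"] = bj,
                      _["matches"] = (double) matches,
                      _["columns"] = (double) columns,
                      _["identity"] = columns > 0 ? 100.0 * matches / columns : 0.0);
}
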