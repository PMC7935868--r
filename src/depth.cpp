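#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <deque>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base2(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

static inline uint64_t mixhash(uint64_t x) {
  x ^= x >> 33; x *= 0xff51afd7ed558ccdULL;
  x ^= x >> 33; x *= 0xc4ceb9fe1a85ec53ULL;
  x ^= x >> 33; return x;
}

struct Mini { int pos; uint64_t hash; bool rc; };

// (w,k)-minimizers of canonical k-mers; k-mers containing N are skipped.
static void minimizers(const std::string& s, int k, int w, std::vector<Mini>& out) {
  const int n = (int) s.size();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t fh = 0, rh = 0;
  int run = 0;
  std::deque<Mini> win;
  int last_emit = -1;
  for (int i = 0; i < n; ++i) {
    int c = base2(s[(size_t) i]);
    if (c < 0) { run = 0; fh = 0; rh = 0; win.clear(); continue; }
    fh = ((fh << 2) | (uint64_t) c) & mask;
    rh = (rh >> 2) | (((uint64_t) (3 - c)) << (2 * (k - 1)));
    if (++run < k) continue;
    int pos = i - k + 1;
    bool rc = rh < fh;
    uint64_t h = mixhash(rc ? rh : fh);
    Mini m; m.pos = pos; m.hash = h; m.rc = rc;
    while (!win.empty() && win.back().hash >= h) win.pop_back();
    win.push_back(m);
    while (win.front().pos <= pos - w) win.pop_front();
    if (run >= k + w - 1 || pos == 0) {
      if (win.front().pos != last_emit) {
        out.push_back(win.front());
        last_emit = win.front().pos;
      }
    }
  }
}

// Minimizer-vote read mapper used for depth profiling.  Each read is
// assigned once, to its best-voted (target, strand, diagonal) bucket; the
// best collinear chain in that bucket is projected to full read length and
// per-base depth incremented over the projected span.  Circular targets are
// indexed as their doubled sequence and depth is folded modulo length.
// [[Rcpp::export]]
List map_reads_cpp(CharacterVector targets, LogicalVector circular,
                   CharacterVector reads, int k = 15, int w = 10,
                   int min_seeds = 3) {
  const int nt = targets.size();
  std::vector<std::string> tseq(nt);
  std::vector<int> tlen(nt);
  std::unordered_map<uint64_t, std::vector<uint64_t> > idx;
  for (int t = 0; t < nt; ++t) {
    std::string s = as<std::string>(targets[t]);
    tlen[t] = (int) s.size();
    if (circular[t]) s += s;
    tseq[t] = s;
    std::vector<Mini> mm;
    minimizers(s, k, w, mm);
    for (size_t u = 0; u < mm.size(); ++u) {
      uint64_t packed = ((uint64_t) t << 40) | ((uint64_t) mm[u].pos << 1) |
                        (mm[u].rc ? 1ULL : 0ULL);
      idx[mm[u].hash].push_back(packed);
    }
  }
  List depth(nt);
  std::vector<IntegerVector> dv;
  for (int t = 0; t < nt; ++t) {
    IntegerVector v(tlen[t]);
    dv.push_back(v);
    depth[t] = v;
  }
  const int nr = reads.size();
  IntegerVector r_target(nr), r_tstart(nr), r_tend(nr), r_qbases(nr), r_nseeds(nr);
  struct Hit { int tid; int rs; int tpos; int qadj; };
  std::vector<Hit> hits;
  std::unordered_map<uint64_t, int> votes;
  for (int r = 0; r < nr; ++r) {
    std::string q = as<std::string>(reads[r]);
    const int rlen = (int) q.size();
    std::vector<Mini> qm;
    minimizers(q, k, w, qm);
    hits.clear(); votes.clear();
    for (size_t u = 0; u < qm.size(); ++u) {
      std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator it =
        idx.find(qm[u].hash);
      if (it == idx.end()) continue;
      if (it->second.size() > 200) continue;   // drop hyper-repetitive seeds
      for (size_t v = 0; v < it->second.size(); ++v) {
        uint64_t p = it->second[v];
        int tid = (int) (p >> 40);
        int tpos = (int) ((p >> 1) & 0x7FFFFFFFULL);
        bool trc = (p & 1ULL) != 0;
        int rs = (trc != qm[u].rc) ? 1 : 0;
        int qadj = rs ? (rlen - k - qm[u].pos) : qm[u].pos;
        Hit h; h.tid = tid; h.rs = rs; h.tpos = tpos; h.qadj = qadj;
        hits.push_back(h);
        int diag = tpos - qadj;
        uint64_t key = ((uint64_t) tid << 33) | ((uint64_t) rs << 32) |
                       (uint64_t) (uint32_t) ((diag >> 9) + 0x40000000);
        votes[key]++;
      }
    }
    r_target[r] = NA_INTEGER; r_tstart[r] = NA_INTEGER; r_tend[r] = NA_INTEGER;
    r_qbases[r] = 0; r_nseeds[r] = 0;
    if (hits.empty()) continue;
    uint64_t bestkey = 0; int bestv = -1;
    for (std::unordered_map<uint64_t, int>::const_iterator it = votes.begin();
         it != votes.end(); ++it) {
      if (it->second > bestv ||
          (it->second == bestv && it->first < bestkey)) {
        bestv = it->second; bestkey = it->first;
      }
    }
    int btid = (int) (bestkey >> 33);
    int brs = (int) ((bestkey >> 32) & 1ULL);
    int bbin = (int) (uint32_t) (bestkey & 0xFFFFFFFFULL) - 0x40000000;
    // gather bucket +/- one neighbour, chain greedily along the read
    std::vector<Hit> sel;
    for (size_t u = 0; u < hits.size(); ++u) {
      const Hit& h = hits[u];
      if (h.tid != btid || h.rs != brs) continue;
      int bin = (h.tpos - h.qadj) >> 9;
      if (bin < bbin - 1 || bin > bbin + 1) continue;
      sel.push_back(h);
    }
    if ((int) sel.size() < min_seeds) continue;
    std::sort(sel.begin(), sel.end(),
              [](const Hit& x, const Hit& y) {
                return x.qadj < y.qadj || (x.qadj == y.qadj && x.tpos < y.tpos);
              });
    int first_t = -1, first_q = -1, last_t = -1, last_q = -1, nseed = 0;
    for (size_t u = 0; u < sel.size(); ++u) {
      const Hit& h = sel[u];
      if (nseed == 0) {
        first_t = last_t = h.tpos; first_q = last_q = h.qadj; ++nseed;
      } else if (h.tpos >= last_t - 50 && h.tpos - last_t <= 5000 &&
                 h.qadj - last_q <= 5000) {
        last_t = h.tpos; last_q = h.qadj; ++nseed;
      }
    }
    if (nseed < min_seeds) continue;
    const int L = tlen[btid];
    const int Ltot = (int) tseq[btid].size();
    // project the chain to (approximately) full read length, but cap the
    // unseeded extension so clipped reads (e.g. spanning a deletion on the
    // other haplotype) do not smear depth past their matched region
    const int CAP = 150;
    int lext = first_q < CAP ? first_q : CAP;
    int rext = rlen - last_q;
    if (rext > CAP + k) rext = CAP + k;
    int tstart = first_t - lext;
    int tend = last_t + rext;
    if (tstart < 0) tstart = 0;
    if (tend > Ltot) tend = Ltot;
    if (tend - tstart > L) tend = tstart + L;
    IntegerVector& D = dv[btid];
    for (int p = tstart; p < tend; ++p) D[p % L]++;
    r_target[r] = btid + 1;
    r_tstart[r] = tstart % L;
    r_tend[r] = tend;          // may exceed L for wrapped circular spans
    r_qbases[r] = (last_q + k) - first_q;
    r_nseeds[r] = nseed;
  }
  DataFrame rd = DataFrame::create(
    _["target"] = r_target, _["tstart"] = r_tstart, _["tend"] = r_tend,
    _["qbases"] = r_qbases, _["nseeds"] = r_nseeds);
  return List::create(_["depth"] = depth, _["reads"] = rd);
}

// TRUE for reads sharing at least one canonical k-mer with `region`.
// [[Rcpp::export]]
LogicalVector kmer_region_filter_cpp(CharacterVector reads, std::string region,
                                     int k = 15) {
  std::unordered_set<uint64_t> keys;
  {
    std::vector<Mini> mm;   // use every k-mer, not minimizers: w = 1
    minimizers(region, k, 1, mm);
    for (size_t u = 0; u < mm.size(); ++u) keys.insert(mm[u].hash);
  }
  const int nr = reads.size();
  LogicalVector out(nr);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (int r = 0; r < nr; ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int n = (int) LENGTH(STRING_ELT(reads, r));
    uint64_t fh = 0, rh = 0; int run = 0; bool hit = false;
    for (int i = 0; i < n && !hit; ++i) {
      int c = base2(s[i]);
      if (c < 0) { run = 0; fh = 0; rh = 0; continue; }
      fh = ((fh << 2) | (uint64_t) c) & mask;
      rh = (rh >> 2) | (((uint64_t) (3 - c)) << (2 * (k - 1)));
      if (++run < k) continue;
      uint64_t h = mixhash(rh < fh ? rh : fh);
      if (keys.count(h)) hit = true;
    }
    out[r] = hit;
  }
  return out;
}

// Per-base i.i.d. substitutions, insertions and deletions, drawn from R's
// RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, double sub, double ins,
                                double del) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  const int n = seqs.size();
  CharacterVector out(n);
  std::string res;
  for (int s = 0; s < n; ++s) {
    const char* x = CHAR(STRING_ELT(seqs, s));
    int m = (int) LENGTH(STRING_ELT(seqs, s));
    res.clear();
    res.reserve((size_t) (m * (1.0 + ins) + 16));
    for (int i = 0; i < m; ++i) {
      double u = unif_rand();
      if (u < del) {
        // deleted
      } else if (u < del + sub) {
        int c = base2(x[i]);
        if (c < 0) res.push_back(x[i]);
        else res.push_back(B[(c + 1 + (int) (unif_rand() * 3)) & 3]);
      } else {
        res.push_back(x[i]);
      }
      if (unif_rand() < ins)
        res.push_back(B[(int) (unif_rand() * 4) & 3]);
    }
    out[s] = res;
  }
  return out;
}
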