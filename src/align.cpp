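#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Seed-and-extend local alignment on DNA strings.
//
// Seeds are exact seed_k-mers (2-bit encoded; windows containing non-ACGT
// are skipped).  Seed hits are grouped into near-diagonal bands, each band
// is extended ungapped at both ends with an X-drop rule, and the banded
// region is then re-aligned with a unit-cost banded global DP (match +1,
// mismatch/gap -1) whose traceback yields match counts for the identity.
//
// Coordinates are 0-based half-open on the forward strands of the inputs;
// for '-' hits the query coordinates refer to the original (un-reversed)
// query sequence.

namespace {

const int BAND_TOL = 20;      // max diagonal drift within one seed band
const int MAX_SEED_GAP = 500; // split band when consecutive seeds are farther
const int XDROP = 20;         // ungapped extension drop-off
const int BAND_PAD = 16;      // extra half-width for the banded DP

inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

inline bool base_eq(char a, char b) {
  int x = base2bits(a), y = base2bits(b);
  return x >= 0 && x == y; // N never matches
}

struct SeedHit { int q, t; };

struct Candidate {
  int qs, qe, ts, te; // half-open region on query/target
};

struct AlnResult {
  int qs, qe, ts, te;
  int matches, columns;
};

// k-mer index of the target
void index_kmers(const std::string& s, int k,
                 std::unordered_map<uint64_t, std::vector<int> >& idx) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)b) & mask;
    if (++run >= k) idx[kmer].push_back(i - k + 1);
  }
}

std::vector<SeedHit> collect_hits(const std::string& q, const std::string& t, int k) {
  std::unordered_map<uint64_t, std::vector<int> > idx;
  index_kmers(t, k, idx);
  std::vector<SeedHit> hits;
  const int n = (int)q.size();
  uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bits(q[i]);
    if (b < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      std::unordered_map<uint64_t, std::vector<int> >::const_iterator it = idx.find(kmer);
      if (it != idx.end()) {
        int qpos = i - k + 1;
        for (size_t j = 0; j < it->second.size(); ++j) {
          SeedHit h; h.q = qpos; h.t = it->second[j];
          hits.push_back(h);
        }
      }
    }
  }
  return hits;
}

// group seed hits into near-diagonal colinear bands
std::vector<Candidate> band_candidates(std::vector<SeedHit>& hits, int k) {
  std::vector<Candidate> out;
  if (hits.empty()) return out;
  std::sort(hits.begin(), hits.end(), [](const SeedHit& a, const SeedHit& b) {
    int da = a.q - a.t, db = b.q - b.t;
    if (da != db) return da < db;
    return a.q < b.q;
  });
  size_t start = 0;
  for (size_t i = 1; i <= hits.size(); ++i) {
    bool brk = (i == hits.size());
    if (!brk) {
      int d0 = hits[i - 1].q - hits[i - 1].t;
      int d1 = hits[i].q - hits[i].t;
      if (d1 - d0 > BAND_TOL) brk = true;
    }
    if (brk) {
      // within the diagonal band, order by q and split on large gaps
      std::sort(hits.begin() + start, hits.begin() + i,
                [](const SeedHit& a, const SeedHit& b) { return a.q < b.q; });
      size_t s2 = start;
      for (size_t j = start + 1; j <= i; ++j) {
        bool brk2 = (j == i) || (hits[j].q - hits[j - 1].q > MAX_SEED_GAP) ||
                    (hits[j].t < hits[j - 1].t);
        if (brk2) {
          Candidate c;
          c.qs = hits[s2].q; c.ts = hits[s2].t;
          c.qe = hits[j - 1].q + k; c.te = hits[j - 1].t + k;
          out.push_back(c);
          s2 = j;
        }
      }
      start = i;
    }
  }
  return out;
}

// ungapped X-drop extension of a region at both ends
void xdrop_extend(const std::string& q, const std::string& t, Candidate& c) {
  int score = 0, best = 0, besti = 0;
  // left
  int i = 1;
  while (c.qs - i >= 0 && c.ts - i >= 0) {
    score += base_eq(q[c.qs - i], t[c.ts - i]) ? 1 : -1;
    if (score > best) { best = score; besti = i; }
    if (best - score > XDROP) break;
    ++i;
  }
  c.qs -= besti; c.ts -= besti;
  // right
  score = 0; best = 0; besti = 0; i = 0;
  while (c.qe + i < (int)q.size() && c.te + i < (int)t.size()) {
    score += base_eq(q[c.qe + i], t[c.te + i]) ? 1 : -1;
    if (score > best) { best = score; besti = i + 1; }
    if (best - score > XDROP) break;
    ++i;
  }
  c.qe += besti; c.te += besti;
}

// banded unit-cost global alignment of the candidate region with traceback;
// returns matches and alignment columns
bool banded_align(const std::string& q, const std::string& t, const Candidate& c,
                  AlnResult& res) {
  const int m = c.qe - c.qs, n = c.te - c.ts;
  if (m <= 0 || n <= 0) return false;
  const int delta = n - m;
  const int lo = std::min(0, delta) - BAND_PAD;
  const int hi = std::max(0, delta) + BAND_PAD;
  const int W = hi - lo + 1;
  const int NEG = -1000000000;
  // dp[i][d] with d = j - i - lo
  std::vector<int> prev((size_t)W, NEG), cur((size_t)W, NEG);
  std::vector<int8_t> ptr((size_t)(m + 1) * W, 0); // 0 diag, 1 up(query gap? see below), 2 left
  // init row i = 0: j = d + lo must be in [0, n]
  for (int d = 0; d < W; ++d) {
    int j = d + lo;
    if (j >= 0 && j <= n) { prev[d] = -j; ptr[d] = 2; }
  }
  for (int i = 1; i <= m; ++i) {
    for (int d = 0; d < W; ++d) cur[d] = NEG;
    for (int d = 0; d < W; ++d) {
      int j = i + d + lo;
      if (j < 0 || j > n) continue;
      int bestv = NEG; int8_t bp = 0;
      // diagonal: (i-1, j-1) -> prev[d]
      if (j >= 1 && prev[d] != NEG) {
        int sc = prev[d] + (base_eq(q[c.qs + i - 1], t[c.ts + j - 1]) ? 1 : -1);
        if (sc > bestv) { bestv = sc; bp = 0; }
      }
      // up: (i-1, j) -> prev[d+1] (gap in target consumes query base)
      if (d + 1 < W && prev[d + 1] != NEG) {
        int sc = prev[d + 1] - 1;
        if (sc > bestv) { bestv = sc; bp = 1; }
      }
      // left: (i, j-1) -> cur[d-1] (gap in query consumes target base)
      if (d - 1 >= 0 && cur[d - 1] != NEG) {
        int sc = cur[d - 1] - 1;
        if (sc > bestv) { bestv = sc; bp = 2; }
      }
      cur[d] = bestv;
      ptr[(size_t)i * W + d] = bp;
    }
    std::swap(prev, cur);
  }
  // traceback from (m, n)
  int dend = n - m - lo;
  if (dend < 0 || dend >= W || prev[dend] == NEG) return false;
  int i = m, j = n, matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    int d = j - i - lo;
    if (d < 0 || d >= W) return false;
    int8_t bp = ptr[(size_t)i * W + d];
    if (i > 0 && j > 0 && bp == 0) {
      if (base_eq(q[c.qs + i - 1], t[c.ts + j - 1])) ++matches;
      --i; --j; ++cols;
    } else if (i > 0 && bp == 1) {
      --i; ++cols;
    } else if (j > 0) {
      --j; ++cols;
    } else {
      --i; ++cols;
    }
  }
  res.qs = c.qs; res.qe = c.qe; res.ts = c.ts; res.te = c.te;
  res.matches = matches; res.columns = cols;
  return true;
}

void align_one_strand(const std::string& q, const std::string& t, int seed_k,
                      double min_identity, int min_len,
                      std::vector<AlnResult>& results) {
  std::vector<SeedHit> hits = collect_hits(q, t, seed_k);
  std::vector<Candidate> cands = band_candidates(hits, seed_k);
  for (size_t i = 0; i < cands.size(); ++i) {
    Candidate c = cands[i];
    xdrop_extend(q, t, c);
    if (c.qe - c.qs < min_len) continue; // cannot reach min_len
    AlnResult r;
    if (!banded_align(q, t, c, r)) continue;
    double ident = r.columns > 0 ? (double)r.matches / (double)r.columns : 0.0;
    if (ident >= min_identity && (r.qe - r.qs) >= min_len) results.push_back(r);
  }
}

bool overlaps(const AlnResult& a, const AlnResult& b) {
  bool qo = a.qs < b.qe && b.qs < a.qe;
  bool to = a.ts < b.te && b.ts < a.te;
  return qo || to;
}

} // namespace

// [[Rcpp::export(name = ".cpp_seed_align")]]
DataFrame cpp_seed_align(std::string query, std::string target,
                         std::string query_rc,
                         int seed_k, double min_identity, int min_len,
                         bool both_strands) {
  std::vector<AlnResult> fwd, rev;
  align_one_strand(query, target, seed_k, min_identity, min_len, fwd);
  if (both_strands && !query_rc.empty())
    align_one_strand(query_rc, target, seed_k, min_identity, min_len, rev);

  struct Tagged { AlnResult r; bool minus; };
  std::vector<Tagged> all;
  const int qlen = (int)query.size();
  for (size_t i = 0; i < fwd.size(); ++i) { Tagged t; t.r = fwd[i]; t.minus = false; all.push_back(t); }
  for (size_t i = 0; i < rev.size(); ++i) {
    // map rc coordinates back to the forward query
    Tagged t; t.r = rev[i]; t.minus = true;
    int qs = qlen - rev[i].qe, qe = qlen - rev[i].qs;
    t.r.qs = qs; t.r.qe = qe;
    all.push_back(t);
  }
  std::sort(all.begin(), all.end(), [](const Tagged& a, const Tagged& b) {
    if (a.r.matches != b.r.matches) return a.r.matches > b.r.matches;
    if (a.r.qs != b.r.qs) return a.r.qs < b.r.qs;
    return a.r.ts < b.r.ts;
  });
  std::vector<Tagged> kept;
  for (size_t i = 0; i < all.size(); ++i) {
    bool ok = true;
    for (size_t j = 0; j < kept.size(); ++j)
      if (overlaps(all[i].r, kept[j].r)) { ok = false; break; }
    if (ok) kept.push_back(all[i]);
  }
  std::sort(kept.begin(), kept.end(), [](const Tagged& a, const Tagged& b) {
    if (a.r.qs != b.r.qs) return a.r.qs < b.r.qs;
    return a.r.ts < b.r.ts;
  });

  const int nres = (int)kept.size();
  IntegerVector q_start(nres), q_end(nres), t_start(nres), t_end(nres), aln_len(nres), matches(nres);
  NumericVector identity(nres);
  CharacterVector strand(nres);
  for (int i = 0; i < nres; ++i) {
    const AlnResult& r = kept[i].r;
    q_start[i] = r.qs; q_end[i] = r.qe; t_start[i] = r.ts; t_end[i] = r.te;
    aln_len[i] = r.qe - r.qs;
    matches[i] = r.matches;
    identity[i] = r.columns > 0 ? (double)r.matches / (double)r.columns : 0.0;
    strand[i] = kept[i].minus ? "-" : "+";
  }
  return DataFrame::create(
    Named("q_start") = q_start, Named("q_end") = q_end,
    Named("t_start") = t_start, Named("t_end") = t_end,
    Named("identity") = identity, Named("aln_len") = aln_len,
    Named("matches") = matches, Named("strand") = strand,
    Named("stringsAsFactors") = false);
}
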