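// Low-level sequence kernels: canonical k-mer counting, unitig extraction
// from a bubble-preserving de Bruijn graph, exact-seed read mapping, and
// unique-anchor matching for pairwise scaffold comparison.
//
// Conventions shared with the R layer:
//  - bases are {A,C,G,T}; any other character breaks a k-mer window
//  - k-mers are 2-bit packed (A=0,C=1,G=2,T=3), k <= 32
//  - the canonical form is the lexicographic minimum of a k-mer and its
//    reverse complement
//  - all positions handed to/from R are 0-based

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <deque>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char DECODE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t kmask(int k) {
  return (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

static inline uint64_t rc_kmer(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

static inline uint64_t canon_kmer(uint64_t x, int k) {
  uint64_t r = rc_kmer(x, k);
  return x < r ? x : r;
}

// Count canonical k-mers over every clean window of every read.
static void count_windows(const CharacterVector& reads, int k,
                          std::unordered_map<uint64_t, uint32_t>& cnt,
                          double* total_windows) {
  const uint64_t mask = kmask(k);
  const int shift = 2 * (k - 1);
  double tot = 0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    uint64_t f = 0, rcv = 0;
    int valid = 0;
    for (const char* p = s; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) { valid = 0; f = 0; rcv = 0; continue; }
      f = ((f << 2) | (uint64_t)c) & mask;
      rcv = (rcv >> 2) | ((uint64_t)(3 - c) << shift);
      if (++valid >= k) {
        uint64_t key = f < rcv ? f : rcv;
        ++cnt[key];
        tot += 1;
      }
    }
  }
  if (total_windows) *total_windows = tot;
}

// [[Rcpp::export]]
List cpp_kmer_hist(CharacterVector reads, int k) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  std::unordered_map<uint64_t, uint32_t> cnt;
  double total = 0;
  count_windows(reads, k, cnt, &total);
  std::unordered_map<uint32_t, double> hist;
  for (auto& kv : cnt) hist[kv.second] += 1;
  std::vector<uint32_t> depths;
  depths.reserve(hist.size());
  for (auto& kv : hist) depths.push_back(kv.first);
  std::sort(depths.begin(), depths.end());
  IntegerVector d(depths.size());
  NumericVector n(depths.size());
  for (size_t i = 0; i < depths.size(); ++i) {
    d[i] = depths[i];
    n[i] = hist[depths[i]];
  }
  return List::create(_["depth"] = d, _["count"] = n,
                      _["total_kmers"] = total,
                      _["distinct_kmers"] = (double)cnt.size());
}

// Build the k-mer de Bruijn graph (nodes = canonical k-mers with count >=
// min_count, no bubble or tip removal) and extract maximal non-branching
// paths (unitigs) plus the junction adjacency between unitig ends.
//
// Adjacency rows are directed "out of an end": (u, u_end, v, v_end) means
// leaving unitig u through end u_end ("R" = rightwards in the stored
// orientation, "L" = leftwards) enters unitig v at end v_end ("L" = v is
// traversed forward, "R" = backward).
// [[Rcpp::export]]
List cpp_build_unitigs(CharacterVector reads, int k, int min_count) {
  if (k < 3 || k > 31) stop("k must be in [3, 31] for graph construction");
  if (k % 2 == 0) stop("k must be odd (avoids palindromic k-mers)");
  const uint64_t mask = kmask(k);

  std::unordered_map<uint64_t, uint32_t> cnt;
  count_windows(reads, k, cnt, nullptr);
  for (auto it = cnt.begin(); it != cnt.end();) {
    if ((int)it->second < min_count) it = cnt.erase(it);
    else ++it;
  }

  // deterministic iteration order
  std::vector<uint64_t> keys;
  keys.reserve(cnt.size());
  for (auto& kv : cnt) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());

  auto present = [&](uint64_t x) -> bool {
    return cnt.find(canon_kmer(x, k)) != cnt.end();
  };
  auto successors = [&](uint64_t x, uint64_t* out) -> int {
    int n = 0;
    uint64_t base = (x << 2) & mask;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t y = base | b;
      if (present(y)) out[n++] = y;
    }
    return n;
  };
  auto pred_count = [&](uint64_t x) -> int {
    uint64_t tmp[4];
    return successors(rc_kmer(x, k), tmp);
  };

  std::unordered_set<uint64_t> vis;
  vis.reserve(cnt.size() * 2);
  // canonical k-mer -> (unitig, pos, strand): strand 1 iff the k-mer as
  // oriented inside the unitig equals its canonical form
  struct Loc { uint32_t u; uint32_t pos; uint8_t strand; };
  std::unordered_map<uint64_t, Loc> loc;
  loc.reserve(cnt.size() * 2);

  std::vector<std::string> useq;
  std::vector<double> ucov;
  std::vector<int> unk;
  std::vector<uint64_t> first_k, last_k; // oriented terminal k-mers

  uint64_t S[4];
  for (uint64_t c : keys) {
    if (vis.count(c)) continue;
    std::deque<uint64_t> chain;
    chain.push_back(c);
    vis.insert(c);
    // forward
    uint64_t x = c;
    while (true) {
      if (successors(x, S) != 1) break;
      uint64_t y = S[0];
      if (pred_count(y) != 1) break;
      uint64_t cy = canon_kmer(y, k);
      if (vis.count(cy)) break;
      chain.push_back(y);
      vis.insert(cy);
      x = y;
    }
    // backward (extend the reverse complement of the front, prepend)
    x = rc_kmer(chain.front(), k);
    while (true) {
      if (successors(x, S) != 1) break;
      uint64_t y = S[0];
      if (pred_count(y) != 1) break;
      uint64_t cy = canon_kmer(y, k);
      if (vis.count(cy)) break;
      chain.push_front(rc_kmer(y, k));
      vis.insert(cy);
      x = y;
    }

    uint32_t uid = (uint32_t)useq.size();
    std::string seq;
    seq.reserve(chain.size() + k - 1);
    double cov = 0;
    uint32_t pos = 0;
    for (uint64_t km : chain) {
      uint64_t cn = canon_kmer(km, k);
      cov += cnt[cn];
      loc[cn] = Loc{uid, pos, (uint8_t)(km == cn ? 1 : 0)};
      if (pos == 0) {
        for (int i = k - 1; i >= 0; --i)
          seq.push_back(DECODE[(km >> (2 * i)) & 3ULL]);
      } else {
        seq.push_back(DECODE[km & 3ULL]);
      }
      ++pos;
    }
    useq.push_back(seq);
    ucov.push_back(cov / (double)chain.size());
    unk.push_back((int)chain.size());
    first_k.push_back(chain.front());
    last_k.push_back(chain.back());
  }

  // junction adjacency
  std::vector<int> e_u, e_v;
  std::vector<std::string> e_uend, e_vend;
  for (size_t u = 0; u < useq.size(); ++u) {
    for (int side = 0; side < 2; ++side) {
      uint64_t x = (side == 0) ? last_k[u] : rc_kmer(first_k[u], k);
      int n = successors(x, S);
      for (int i = 0; i < n; ++i) {
        uint64_t y = S[i];
        uint64_t cy = canon_kmer(y, k);
        auto it = loc.find(cy);
        if (it == loc.end()) continue;
        const Loc& L = it->second;
        bool y_is_forward_in_v = ((y == cy) == (L.strand == 1));
        uint32_t vlen = (uint32_t)unk[L.u];
        std::string vend;
        if (y_is_forward_in_v && L.pos == 0) vend = "L";
        else if (!y_is_forward_in_v && L.pos == vlen - 1) vend = "R";
        else continue; // mid-unitig entry (cycle artefact), not a junction
        e_u.push_back((int)u + 1);
        e_uend.push_back(side == 0 ? "R" : "L");
        e_v.push_back((int)L.u + 1);
        e_vend.push_back(vend);
      }
    }
  }

  double retained_total = 0;
  for (auto& kv : cnt) retained_total += kv.second;

  return List::create(
    _["seq"] = wrap(useq),
    _["coverage"] = wrap(ucov),
    _["n_kmers"] = wrap(unk),
    _["edge_u"] = wrap(e_u), _["edge_u_end"] = wrap(e_uend),
    _["edge_v"] = wrap(e_v), _["edge_v_end"] = wrap(e_vend),
    _["distinct_kmers"] = (double)cnt.size(),
    _["retained_count_total"] = retained_total);
}

// Seed index over a set of element sequences: canonical seed -> unique
// (element, pos, strand); seeds occurring at more than one location across
// the whole element set are marked ambiguous and never used.
struct SeedIndex {
  std::unordered_map<uint64_t, int64_t> map; // packed, -1 = ambiguous
  int L;
};

static void build_seed_index(const CharacterVector& elements, int L,
                             SeedIndex& idx) {
  idx.L = L;
  const uint64_t mask = kmask(L);
  const int shift = 2 * (L - 1);
  for (R_xlen_t e = 0; e < elements.size(); ++e) {
    const char* s = CHAR(STRING_ELT(elements, e));
    uint64_t f = 0, rcv = 0;
    int valid = 0;
    int64_t i = -1;
    for (const char* p = s; *p; ++p) {
      ++i;
      int c = base_code(*p);
      if (c < 0) { valid = 0; f = 0; rcv = 0; continue; }
      f = ((f << 2) | (uint64_t)c) & mask;
      rcv = (rcv >> 2) | ((uint64_t)(3 - c) << shift);
      if (++valid < L) continue;
      uint64_t key = f < rcv ? f : rcv;
      int64_t strand = (key == f) ? 1 : 0;
      int64_t pos = i - L + 1;
      int64_t packed = ((int64_t)e << 34) | (pos << 2) | (strand << 1);
      auto it = idx.map.find(key);
      if (it == idx.map.end()) idx.map[key] = packed;
      else it->second = -1;
    }
  }
}

// Map reads onto elements by runs of consecutive unique seed matches on a
// consistent diagonal. A read may touch several elements (it can span
// junctions between short elements); each touch with a run of >= min_run
// consecutive seeds is reported. Ambiguous seeds are skipped entirely.
// Returns (read, elem, strand, pos, nseeds): pos is the 0-based start of
// the (whole) read on the element implied by the seed diagonal; strand +1
// means the read aligns forward, -1 reverse-complemented.
// [[Rcpp::export]]
DataFrame cpp_map_touches(CharacterVector reads, CharacterVector elements,
                          int seed_len, int min_run) {
  if (seed_len < 5 || seed_len > 32) stop("seed_len must be in [5, 32]");
  SeedIndex idx;
  build_seed_index(elements, seed_len, idx);
  const uint64_t mask = kmask(seed_len);
  const int shift = 2 * (seed_len - 1);

  std::vector<int> o_read, o_elem, o_strand, o_nseed;
  std::vector<double> o_pos;

  struct Key { int64_t elem; int m; int64_t diag; };
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int rlen = (int)LENGTH(STRING_ELT(reads, r));
    uint64_t f = 0, rcv = 0;
    int valid = 0;
    // active run per (elem, m, diag); reads are short so linear scan of a
    // small vector of finished runs is fine
    struct Run { int64_t elem; int m; int64_t diag; int len; int maxlen; };
    std::vector<Run> runs;
    Run cur{-1, 0, 0, 0, 0};
    auto flush = [&]() {
      if (cur.elem < 0 || cur.maxlen < min_run) { cur = Run{-1,0,0,0,0}; return; }
      for (auto& R0 : runs) {
        if (R0.elem == cur.elem && R0.m == cur.m && R0.diag == cur.diag) {
          if (cur.maxlen > R0.maxlen) R0.maxlen = cur.maxlen;
          cur = Run{-1,0,0,0,0};
          return;
        }
      }
      runs.push_back(cur);
      cur = Run{-1,0,0,0,0};
    };
    int64_t i = -1;
    for (const char* p = s; *p; ++p) {
      ++i;
      int c = base_code(*p);
      if (c < 0) { valid = 0; f = 0; rcv = 0; flush(); continue; }
      f = ((f << 2) | (uint64_t)c) & mask;
      rcv = (rcv >> 2) | ((uint64_t)(3 - c) << shift);
      if (++valid < seed_len) continue;
      uint64_t key = f < rcv ? f : rcv;
      auto it = idx.map.find(key);
      int64_t qpos = i - seed_len + 1;
      if (it == idx.map.end() || it->second < 0) { flush(); continue; }
      int64_t packed = it->second;
      int64_t elem = packed >> 34;
      int64_t pos = (packed >> 2) & ((1LL << 32) - 1);
      int s_elem = (int)((packed >> 1) & 1);
      int qs = (key == f) ? 1 : 0;
      int m = (qs == s_elem) ? 1 : -1;
      int64_t diag = (m == 1) ? (pos - qpos) : (pos + qpos);
      if (cur.elem == elem && cur.m == m && cur.diag == diag) {
        cur.len++;
        if (cur.len > cur.maxlen) cur.maxlen = cur.len;
      } else {
        flush();
        cur = Run{elem, m, diag, 1, 1};
      }
    }
    flush();
    for (auto& R0 : runs) {
      double pos0;
      if (R0.m == 1) pos0 = (double)R0.diag;
      else pos0 = (double)R0.diag + seed_len - rlen;
      o_read.push_back((int)r + 1);
      o_elem.push_back((int)R0.elem + 1);
      o_strand.push_back(R0.m);
      o_pos.push_back(pos0);
      o_nseed.push_back(R0.maxlen);
    }
  }
  return DataFrame::create(_["read"] = wrap(o_read), _["elem"] = wrap(o_elem),
                           _["strand"] = wrap(o_strand), _["pos"] = wrap(o_pos),
                           _["nseeds"] = wrap(o_nseed));
}

// Matched unique L-mers between two sequences (a MUM-like anchor seed set):
// positions qpos/spos are 0-based starts on the forward strands. strand -1
// means A[qpos, qpos+L) equals the reverse complement of B[spos, spos+L).
// Only L-mers occurring exactly once in A (over both strands) and exactly
// once in B are reported.
// [[Rcpp::export]]
DataFrame cpp_unique_matches(CharacterVector seqA, CharacterVector seqB, int L) {
  if (L < 5 || L > 32) stop("anchor length must be in [5, 32]");
  SeedIndex ia, ib;
  build_seed_index(seqA, L, ia);
  build_seed_index(seqB, L, ib);
  std::vector<double> qpos, spos;
  std::vector<int> strand;
  std::vector<uint64_t> keys;
  keys.reserve(ia.map.size());
  for (auto& kv : ia.map) if (kv.second >= 0) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  for (uint64_t key : keys) {
    auto itb = ib.map.find(key);
    if (itb == ib.map.end() || itb->second < 0) continue;
    int64_t pa = ia.map[key];
    int64_t pb = itb->second;
    int sa = (int)((pa >> 1) & 1), sb = (int)((pb >> 1) & 1);
    qpos.push_back((double)((pa >> 2) & ((1LL << 32) - 1)));
    spos.push_back((double)((pb >> 2) & ((1LL << 32) - 1)));
    strand.push_back(sa == sb ? 1 : -1);
  }
  return DataFrame::create(_["qpos"] = wrap(qpos), _["spos"] = wrap(spos),
                           _["strand"] = wrap(strand));
}
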