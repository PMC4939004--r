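// Exact k-mer mappability with a mismatch budget.
//
// For each position p with a full k-mer, count the genome positions q
// (either strand) whose k-mer is within Hamming distance d of p's forward
// k-mer; the score is 1/count.  Exactness at desk scale comes from a
// pigeonhole seed-and-verify scheme: a k-mer within d mismatches of the
// query must match it exactly in at least one of d+1 contiguous parts, so
// exact-part hash lookups enumerate a complete candidate set which is then
// verified by direct Hamming comparison.  Windows containing N are excluded
// (they receive NA upstream).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Key {
  uint64_t hi, lo;
  bool operator==(const Key& o) const { return hi == o.hi && lo == o.lo; }
};
struct KeyHash {
  size_t operator()(const Key& k) const {
    uint64_t h = k.hi * 0x9E3779B97F4A7C15ULL ^ (k.lo + 0x9E3779B97F4A7C15ULL + (k.hi << 6));
    return static_cast<size_t>(h ^ (h >> 29));
  }
};

inline int base2code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

// pack codes[off, off+len) into a 128-bit key (len <= 64)
inline Key pack(const std::vector<int8_t>& codes, int off, int len) {
  Key k{0, 0};
  int half = len / 2;
  for (int i = 0; i < half; ++i) k.hi = (k.hi << 2) | codes[off + i];
  for (int i = half; i < len; ++i) k.lo = (k.lo << 2) | codes[off + i];
  return k;
}

inline int hamming_leq(const std::vector<int8_t>& a, int ai,
                       const std::vector<int8_t>& b, int bi,
                       int k, int d) {
  int mm = 0;
  for (int i = 0; i < k; ++i) {
    if (a[ai + i] != b[bi + i] && ++mm > d) return 0;
  }
  return 1;
}

} // namespace

// genome: character vector of chromosome sequences (uppercase A/C/G/T/N).
// Returns a list of per-chromosome numeric vectors of length L - k + 1 with
// the match count at each position (NA where the window contains N).
// [[Rcpp::export(name = ".mappability_counts")]]
List mappability_counts(CharacterVector genome, int k, int d) {
  if (k < 1) stop("kmer_length must be >= 1");
  if (d < 0) stop("max_mismatches must be >= 0");
  int nchrom = genome.size();

  // encode forward and reverse-complement sequences
  std::vector<std::vector<int8_t>> fwd(nchrom), rcv(nchrom);
  for (int c = 0; c < nchrom; ++c) {
    std::string s = as<std::string>(genome[c]);
    int L = s.size();
    fwd[c].resize(L);
    rcv[c].resize(L);
    for (int i = 0; i < L; ++i) fwd[c][i] = static_cast<int8_t>(base2code(s[i]));
    for (int i = 0; i < L; ++i) {
      int8_t b = fwd[c][L - 1 - i];
      rcv[c][i] = (b < 0) ? int8_t(-1) : int8_t(3 - b);
    }
  }

  // part boundaries: d+1 near-equal contiguous parts of the k-mer
  int nparts = d + 1;
  std::vector<int> poff(nparts + 1);
  for (int j = 0; j <= nparts; ++j) poff[j] = (int)((int64_t)k * j / nparts);
  for (int j = 0; j < nparts; ++j)
    if (poff[j + 1] - poff[j] > 64) stop("k-mer part exceeds 64 bases; increase max_mismatches granularity");

  // windows: (chrom, offset, strand) with no N; strand 0 = forward sequence,
  // strand 1 = a window of the reverse-complement sequence
  struct Win { int32_t chrom, off; uint8_t strand; };
  std::vector<Win> wins;
  std::vector<std::vector<int64_t>> winid_fwd(nchrom); // position -> window id or -1
  for (int c = 0; c < nchrom; ++c) {
    int L = fwd[c].size();
    int nw = L - k + 1;
    if (nw < 1) { winid_fwd[c].assign(std::max(L - k + 1, 0), -1); continue; }
    winid_fwd[c].assign(nw, -1);
    // running count of N to skip invalid windows quickly
    std::vector<int> npre(L + 1, 0);
    for (int i = 0; i < L; ++i) npre[i + 1] = npre[i] + (fwd[c][i] < 0);
    for (int off = 0; off < nw; ++off) {
      if (npre[off + k] - npre[off] == 0) {
        winid_fwd[c][off] = (int64_t)wins.size();
        wins.push_back({c, off, 0});
      }
    }
    for (int off = 0; off < nw; ++off) {
      // rc sequence has Ns at mirrored positions; reuse prefix on rcv
      // window [off, off+k) of rcv corresponds to fwd [L-off-k, L-off)
      if (npre[L - off] - npre[L - off - k] == 0)
        wins.push_back({c, off, 1});
    }
  }

  // hash each part of every window
  std::vector<std::unordered_map<Key, std::vector<int64_t>, KeyHash>> maps(nparts);
  for (int j = 0; j < nparts; ++j) maps[j].reserve(wins.size() * 2);
  for (int64_t w = 0; w < (int64_t)wins.size(); ++w) {
    const Win& W = wins[w];
    const std::vector<int8_t>& seq = W.strand ? rcv[W.chrom] : fwd[W.chrom];
    for (int j = 0; j < nparts; ++j) {
      Key key = pack(seq, W.off + poff[j], poff[j + 1] - poff[j]);
      maps[j][key].push_back(w);
    }
  }

  // query: every valid forward window; candidates deduped per query
  std::vector<int64_t> stamp(wins.size(), -1);
  List out(nchrom);
  int64_t qid = 0;
  for (int c = 0; c < nchrom; ++c) {
    int L = fwd[c].size();
    int nw = L - k + 1;
    NumericVector counts(std::max(nw, 0), NA_REAL);
    for (int off = 0; off < nw; ++off) {
      if (winid_fwd[c][off] < 0) continue; // contains N
      ++qid;
      // set of genome positions matched (dedupe across strands/parts):
      // use a small local vector of (chrom, off) matches
      int64_t npos = 0;
      std::vector<std::pair<int32_t, int32_t>> seen;
      for (int j = 0; j < nparts; ++j) {
        Key key = pack(fwd[c], off + poff[j], poff[j + 1] - poff[j]);
        auto it = maps[j].find(key);
        if (it == maps[j].end()) continue;
        for (int64_t w : it->second) {
          if (stamp[w] == qid) continue;
          stamp[w] = qid;
          const Win& W = wins[w];
          const std::vector<int8_t>& seq = W.strand ? rcv[W.chrom] : fwd[W.chrom];
          if (!hamming_leq(fwd[c], off, seq, W.off, k, d)) continue;
          // map to a genome position: forward window off stays; rc window
          // [off, off+k) of rcv is genome position Lw - off - k on that chrom
          int32_t pos = W.strand
            ? (int32_t)(rcv[W.chrom].size()) - W.off - k
            : W.off;
          bool dup = false;
          for (auto& pr : seen)
            if (pr.first == W.chrom && pr.second == pos) { dup = true; break; }
          if (!dup) { seen.push_back({W.chrom, pos}); ++npos; }
        }
      }
      counts[off] = (double)npos;
    }
    out[c] = counts;
  }
  out.attr("names") = genome.attr("names");
  return out;
}
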