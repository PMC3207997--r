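#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Base encoding: A=0 C=1 G=2 T=3, anything else (incl. N) = 4.
// Code 4 never matches any code, including itself.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static std::vector<uint8_t> encode_seq(const char *s, size_t n) {
  std::vector<uint8_t> v(n);
  for (size_t i = 0; i < n; ++i) v[i] = (uint8_t) base_code(s[i]);
  return v;
}

// Exact-seed lookup structure over all seed_len-mers of every entry
// (forward orientation only; minus-strand hits are found by seeding the
// reverse complement of the read).
struct SeedIndex {
  int seed_len;
  std::vector<std::vector<uint8_t>> seqs;
  // seed key -> packed positions (entry << 32 | offset), in scan order
  std::unordered_map<uint64_t, std::vector<uint64_t>> map;
  size_t n_positions;
  int n_short_entries;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector sequences, int seed_len) {
  if (seed_len < 1 || seed_len > 31)
    stop("seed_len must be between 1 and 31");
  SeedIndex *idx = new SeedIndex();
  idx->seed_len = seed_len;
  idx->n_positions = 0;
  idx->n_short_entries = 0;
  const uint64_t mask = (seed_len == 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
  int n = sequences.size();
  idx->seqs.reserve(n);
  for (int e = 0; e < n; ++e) {
    const char *s = CHAR(STRING_ELT(sequences, e));
    size_t len = std::strlen(s);
    idx->seqs.push_back(encode_seq(s, len));
    const std::vector<uint8_t> &v = idx->seqs.back();
    if ((int) len < seed_len) { idx->n_short_entries++; continue; }
    uint64_t key = 0;
    int valid = 0;  // number of consecutive non-N codes ending here
    for (size_t i = 0; i < len; ++i) {
      uint8_t c = v[i];
      if (c > 3) { valid = 0; key = 0; continue; }
      key = ((key << 2) | c) & mask;
      valid++;
      if (valid >= seed_len) {
        uint64_t off = i - (size_t) seed_len + 1;
        idx->map[key].push_back(((uint64_t) e << 32) | off);
        idx->n_positions++;
      }
    }
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP ptr) {
  XPtr<SeedIndex> idx(ptr);
  return List::create(
    _["n_entries"] = (int) idx->seqs.size(),
    _["n_positions"] = (double) idx->n_positions,
    _["n_short_entries"] = idx->n_short_entries,
    _["seed_len"] = idx->seed_len);
}

static inline bool seed_key(const std::vector<uint8_t> &codes, int seed_len,
                            uint64_t &key) {
  key = 0;
  for (int i = 0; i < seed_len; ++i) {
    if (codes[i] > 3) return false;
    key = (key << 2) | codes[i];
  }
  return true;
}

// Align each read with seed-and-extend: candidate placements are exact
// matches of the first seed_len bases (on minus strand, of the reverse
// complement's first seed_len bases); extension is ungapped Hamming
// comparison of the remaining bases; placements with more than
// max_mismatches discarded. Best hit = min (mismatches, entry, strand + < -,
// offset) in lexicographic order. n_hits counts all surviving placements.
// [[Rcpp::export]]
DataFrame cpp_align(SEXP ptr, CharacterVector reads, int max_mismatches,
                    bool both_strands) {
  XPtr<SeedIndex> idx(ptr);
  const int seed_len = idx->seed_len;
  int n = reads.size();
  IntegerVector entry(n, NA_INTEGER), offset(n, NA_INTEGER),
    mismatches(n, NA_INTEGER), nhits(n, 0);
  CharacterVector strand(n, NA_STRING);

  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    size_t rl = std::strlen(s);
    if ((int) rl < seed_len) continue;
    std::vector<uint8_t> fwd = encode_seq(s, rl);
    std::vector<uint8_t> rc(rl);
    for (size_t i = 0; i < rl; ++i) {
      uint8_t c = fwd[rl - 1 - i];
      rc[i] = (c > 3) ? 4 : (uint8_t) (3 - c);
    }
    int best_mm = max_mismatches + 1;
    int best_entry = -1, best_off = -1, best_strand = 0;
    int survivors = 0;
    for (int st = 0; st < (both_strands ? 2 : 1); ++st) {
      const std::vector<uint8_t> &codes = (st == 0) ? fwd : rc;
      uint64_t key;
      if (!seed_key(codes, seed_len, key)) continue;
      auto it = idx->map.find(key);
      if (it == idx->map.end()) continue;
      for (uint64_t packed : it->second) {
        int e = (int) (packed >> 32);
        size_t off = (size_t) (packed & 0xffffffffULL);
        const std::vector<uint8_t> &ref = idx->seqs[e];
        if (off + rl > ref.size()) continue;  // read must fit in entry
        int mm = 0;
        for (size_t i = (size_t) seed_len; i < rl; ++i) {
          uint8_t a = codes[i], b = ref[off + i];
          if (a > 3 || b > 3 || a != b) {
            if (++mm > max_mismatches) break;
          }
        }
        if (mm > max_mismatches) continue;
        survivors++;
        // candidates arrive sorted by (entry, offset) within each strand and
        // + strand is scanned first, so strict '<' on the tuple suffices
        if (mm < best_mm ||
            (mm == best_mm && (e < best_entry ||
              (e == best_entry && (st < best_strand ||
                (st == best_strand && (int) off < best_off)))))) {
          best_mm = mm; best_entry = e; best_off = (int) off; best_strand = st;
        }
      }
    }
    nhits[r] = survivors;
    if (survivors > 0) {
      entry[r] = best_entry + 1;
      offset[r] = best_off;
      strand[r] = (best_strand == 0) ? "+" : "-";
      mismatches[r] = best_mm;
    }
  }
  return DataFrame::create(
    _["entry"] = entry, _["offset"] = offset, _["strand"] = strand,
    _["mismatches"] = mismatches, _["n_hits"] = nhits,
    _["stringsAsFactors"] = false);
}
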