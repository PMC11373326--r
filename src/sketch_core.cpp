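// 64-bit FracMinHash primitives. R has no native unsigned 64-bit integer,
// so hashes cross the R/C++ boundary as decimal strings and every
// hash/threshold/order operation that needs exact uint64 arithmetic lives
// here.
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cstdlib>
#include <string>
#include <vector>
#include <map>
#include <algorithm>

using namespace Rcpp;

// ---- MurmurHash3 x64_128 (Austin Appleby's public-domain algorithm) ----

static inline uint64_t rotl64(uint64_t x, int8_t r) {
  return (x << r) | (x >> (64 - r));
}

static inline uint64_t fmix64(uint64_t k) {
  k ^= k >> 33;
  k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33;
  k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

// returns h1 of the 128-bit digest (the sourmash convention)
static uint64_t murmur3_x64_128_h1(const char *key, int len, uint32_t seed) {
  const uint8_t *data = reinterpret_cast<const uint8_t *>(key);
  const int nblocks = len / 16;

  uint64_t h1 = seed, h2 = seed;
  const uint64_t c1 = 0x87c37b91114253d5ULL;
  const uint64_t c2 = 0x4cf5ad432745937fULL;

  for (int i = 0; i < nblocks; i++) {
    uint64_t k1, k2;
    std::memcpy(&k1, data + i * 16, 8);
    std::memcpy(&k2, data + i * 16 + 8, 8);

    k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
    h1 = rotl64(h1, 27); h1 += h2; h1 = h1 * 5 + 0x52dce729ULL;
    k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
    h2 = rotl64(h2, 31); h2 += h1; h2 = h2 * 5 + 0x38495ab5ULL;
  }

  const uint8_t *tail = data + nblocks * 16;
  uint64_t k1 = 0, k2 = 0;
  switch (len & 15) {
  case 15: k2 ^= static_cast<uint64_t>(tail[14]) << 48; // fall through
  case 14: k2 ^= static_cast<uint64_t>(tail[13]) << 40; // fall through
  case 13: k2 ^= static_cast<uint64_t>(tail[12]) << 32; // fall through
  case 12: k2 ^= static_cast<uint64_t>(tail[11]) << 24; // fall through
  case 11: k2 ^= static_cast<uint64_t>(tail[10]) << 16; // fall through
  case 10: k2 ^= static_cast<uint64_t>(tail[9]) << 8;   // fall through
  case 9:  k2 ^= static_cast<uint64_t>(tail[8]);
           k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2; // fall through
  case 8:  k1 ^= static_cast<uint64_t>(tail[7]) << 56;  // fall through
  case 7:  k1 ^= static_cast<uint64_t>(tail[6]) << 48;  // fall through
  case 6:  k1 ^= static_cast<uint64_t>(tail[5]) << 40;  // fall through
  case 5:  k1 ^= static_cast<uint64_t>(tail[4]) << 32;  // fall through
  case 4:  k1 ^= static_cast<uint64_t>(tail[3]) << 24;  // fall through
  case 3:  k1 ^= static_cast<uint64_t>(tail[2]) << 16;  // fall through
  case 2:  k1 ^= static_cast<uint64_t>(tail[1]) << 8;   // fall through
  case 1:  k1 ^= static_cast<uint64_t>(tail[0]);
           k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
  }

  h1 ^= static_cast<uint64_t>(len);
  h2 ^= static_cast<uint64_t>(len);
  h1 += h2; h2 += h1;
  h1 = fmix64(h1); h2 = fmix64(h2);
  h1 += h2;
  // h2 += h1 completes the digest but only h1 is used
  return h1;
}

// ---- helpers ----

static inline std::string u64_to_string(uint64_t x) {
  char buf[24];
  std::snprintf(buf, sizeof(buf), "%llu", static_cast<unsigned long long>(x));
  return std::string(buf);
}

static inline uint64_t string_to_u64(const char *s) {
  uint64_t x = 0;
  for (; *s >= '0' && *s <= '9'; ++s)
    x = x * 10u + static_cast<uint64_t>(*s - '0');
  return x;
}

// floor((2^64 - 1) / scaled): the FracMinHash retention threshold
static inline uint64_t threshold_for(double scaled) {
  uint64_t sc = static_cast<uint64_t>(scaled);
  return UINT64_MAX / sc;
}

typedef std::map<uint64_t, double> HashCounts;

static List counts_to_list(const HashCounts &acc) {
  const R_xlen_t n = static_cast<R_xlen_t>(acc.size());
  CharacterVector hashes(n);
  NumericVector abund(n);
  R_xlen_t i = 0;
  for (HashCounts::const_iterator it = acc.begin(); it != acc.end(); ++it, ++i) {
    hashes[i] = u64_to_string(it->first);
    abund[i] = it->second;
  }
  return List::create(_["hashes"] = hashes, _["abundance"] = abund);
}

// [[Rcpp::export(name = ".hash_kmers_cpp")]]
CharacterVector hash_kmers_cpp(CharacterVector kmers, int seed) {
  const R_xlen_t n = kmers.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    out[i] = u64_to_string(
        murmur3_x64_128_h1(s, static_cast<int>(std::strlen(s)),
                           static_cast<uint32_t>(seed)));
  }
  return out;
}

// Hash a k-mer multiset (optionally with per-k-mer counts) and retain hashes
// <= floor((2^64-1)/scaled), aggregating counts per retained hash.
// [[Rcpp::export(name = ".sketch_kmers_cpp")]]
List sketch_kmers_cpp(CharacterVector kmers, NumericVector counts,
                      double scaled, int seed) {
  const uint64_t thr = threshold_for(scaled);
  const bool has_counts = counts.size() > 0;
  HashCounts acc;
  const R_xlen_t n = kmers.size();
  for (R_xlen_t i = 0; i < n; i++) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    uint64_t h = murmur3_x64_128_h1(s, static_cast<int>(std::strlen(s)),
                                    static_cast<uint32_t>(seed));
    if (h <= thr)
      acc[h] += has_counts ? counts[i] : 1.0;
  }
  return counts_to_list(acc);
}

// Extract k-mers from peptide strings and sketch them in one pass.
// K-mers containing 'X' (undefined residue) or '*' (stop) are dropped, so
// passing whole translated frames is equivalent to splitting at stops first.
// [[Rcpp::export(name = ".sketch_peptides_cpp")]]
List sketch_peptides_cpp(CharacterVector peptides, int k, double scaled,
                         int seed) {
  const uint64_t thr = threshold_for(scaled);
  HashCounts acc;
  const R_xlen_t n = peptides.size();
  for (R_xlen_t i = 0; i < n; i++) {
    const char *s = CHAR(STRING_ELT(peptides, i));
    const int len = static_cast<int>(std::strlen(s));
    if (len < k) continue;
    // 'bad' = index just past the most recent X/* within the window
    int bad = 0;
    for (int j = 0; j < len; j++) {
      const char c = s[j];
      if (c == 'X' || c == 'x' || c == '*') bad = j + 1;
      const int start = j - k + 1;
      if (start < 0 || start < bad) continue;
      uint64_t h = murmur3_x64_128_h1(s + start, k,
                                      static_cast<uint32_t>(seed));
      if (h <= thr) acc[h] += 1.0;
    }
  }
  return counts_to_list(acc);
}

// Merge pre-hashed (hash, abundance) pairs from several sketches, adding
// abundances; also used to re-filter at a coarser scaled (downsampling).
// [[Rcpp::export(name = ".combine_hashes_cpp")]]
List combine_hashes_cpp(CharacterVector hashes, NumericVector abundance,
                        double scaled) {
  const uint64_t thr = threshold_for(scaled);
  HashCounts acc;
  const R_xlen_t n = hashes.size();
  for (R_xlen_t i = 0; i < n; i++) {
    uint64_t h = string_to_u64(CHAR(STRING_ELT(hashes, i)));
    if (h <= thr) acc[h] += abundance[i];
  }
  return counts_to_list(acc);
}

// [[Rcpp::export(name = ".u64_sort_order_cpp")]]
IntegerVector u64_sort_order_cpp(CharacterVector hashes) {
  const R_xlen_t n = hashes.size();
  std::vector<std::pair<uint64_t, R_xlen_t> > v(n);
  for (R_xlen_t i = 0; i < n; i++)
    v[i] = std::make_pair(string_to_u64(CHAR(STRING_ELT(hashes, i))), i);
  std::sort(v.begin(), v.end());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = static_cast<int>(v[i].second) + 1;
  return out;
}

// which hashes pass the retention threshold for a given scaled
// [[Rcpp::export(name = ".u64_below_threshold_cpp")]]
LogicalVector u64_below_threshold_cpp(CharacterVector hashes, double scaled) {
  const uint64_t thr = threshold_for(scaled);
  const R_xlen_t n = hashes.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = string_to_u64(CHAR(STRING_ELT(hashes, i))) <= thr;
  return out;
}

// [[Rcpp::export(name = ".u64_threshold_cpp")]]
CharacterVector u64_threshold_cpp(double scaled) {
  return CharacterVector::create(u64_to_string(threshold_for(scaled)));
}
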