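#pragma once

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>

// 2-bit packed k-mers, k <= 64 (2k bits fit one unsigned __int128).
typedef unsigned __int128 u128;

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char code_base(int b) { return "ACGT"[b & 3]; }

// msb-first packing, so integer order == lexicographic order with A<C<G<T
struct KmerCodec {
  int k;
  u128 mask;
  int rc_shift;
  explicit KmerCodec(int k_) : k(k_) {
    mask = (k >= 64) ? ~(u128)0 : ((((u128)1) << (2 * k)) - 1);
    rc_shift = 2 * (k - 1);
  }
  void roll(int b, u128 &fwd, u128 &rc) const {
    fwd = ((fwd << 2) | (u128)b) & mask;
    rc = (rc >> 2) | ((u128)(3 - b) << rc_shift);
  }
  // canonical encoding of the window starting at s[w]; false if non-ACGT inside
  bool window(const std::string &s, size_t w, u128 &canon) const {
    u128 f = 0, r = 0;
    for (int j = 0; j < k; ++j) {
      int b = base_code(s[w + j]);
      if (b < 0) return false;
      roll(b, f, r);
    }
    canon = f < r ? f : r;
    return true;
  }
};

inline std::string decode_kmer(u128 e, int k) {
  std::string s((size_t)k, 'A');
  for (int j = k - 1; j >= 0; --j) {
    s[(size_t)j] = code_base((int)(e & 3));
    e >>= 2;
  }
  return s;
}

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// two independent 64-bit digests for double hashing; h2 forced odd
inline void kmer_hash_pair(u128 canon, uint64_t &h1, uint64_t &h2) {
  uint64_t lo = (uint64_t)canon, hi = (uint64_t)(canon >> 64);
  h1 = splitmix64(lo ^ splitmix64(hi ^ 0x8BADF00DDEADBEEFULL));
  h2 = splitmix64(hi ^ splitmix64(lo ^ 0x5EEDC0DE00C0FFEEULL)) | 1ULL;
}

struct U128Hash {
  size_t operator()(u128 x) const {
    return (size_t)splitmix64((uint64_t)x ^ splitmix64((uint64_t)(x >> 64)));
  }
};

// common presence/absence interface for the Bloom filter and the exact oracle set
struct KmerMembership {
  int k;
  explicit KmerMembership(int k_) : k(k_) {}
  virtual bool contains_enc(u128 canon) const = 0;
  virtual ~KmerMembership() {}
};

struct BloomFilter : KmerMembership {
  uint64_t m;
  int h;
  uint64_t n_inserted;
  double p_target;
  std::vector<uint64_t> words;
  BloomFilter(int k_, uint64_t m_, int h_, double p_)
      : KmerMembership(k_), m(m_), h(h_), n_inserted(0), p_target(p_),
        words((size_t)((m_ + 63) / 64), 0ULL) {}
  void insert_enc(u128 canon) {
    uint64_t h1, h2;
    kmer_hash_pair(canon, h1, h2);
    for (int i = 0; i < h; ++i) {
      uint64_t g = (h1 + (uint64_t)i * h2) % m;
      words[(size_t)(g >> 6)] |= (1ULL << (g & 63));
    }
    ++n_inserted;
  }
  bool contains_enc(u128 canon) const override {
    uint64_t h1, h2;
    kmer_hash_pair(canon, h1, h2);
    for (int i = 0; i < h; ++i) {
      uint64_t g = (h1 + (uint64_t)i * h2) % m;
      if (!(words[(size_t)(g >> 6)] & (1ULL << (g & 63)))) return false;
    }
    return true;
  }
};

struct ExactKmerSet : KmerMembership {
  std::unordered_set<u128, U128Hash> set;
  explicit ExactKmerSet(int k_) : KmerMembership(k_) {}
  bool contains_enc(u128 canon) const override { return set.count(canon) != 0; }
};

struct KmerCountStore {
  int k;
  std::unordered_map<u128, uint32_t, U128Hash> counts;
  explicit KmerCountStore(int k_) : k(k_) {}
};

inline void check_k(int k) {
  if (k < 4 || k > 64) Rcpp::stop("k must be between 4 and 64 (got %d)", k);
}

// encode a single k-mer string; stops on length mismatch, false on non-ACGT
inline bool encode_kmer(const std::string &s, const KmerCodec &cod, u128 &canon) {
  if ((int)s.size() != cod.k)
    Rcpp::stop("k-mer length %d does not match k = %d", (int)s.size(), cod.k);
  return cod.window(s, 0, canon);
}
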