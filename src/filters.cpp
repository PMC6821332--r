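#include "kmer_core.h"
using namespace Rcpp;

// ---- plain string utilities ----------------------------------------------

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    int b = base_code(r[i]);
    if (b < 0) stop("non-ACGT character '%c' in k-mer", r[i]);
    r[i] = code_base(3 - b);
  }
  return r;
}

// [[Rcpp::export]]
CharacterVector canonical_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (CharacterVector::is_na(seqs[i])) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) s[j] = (char)toupper(s[j]);
    std::string rc = revcomp_str(s);
    out[i] = (s <= rc) ? s : rc;
  }
  return out;
}

// rolling iteration over all windows; invalid windows flagged, k-mer = NA
// [[Rcpp::export]]
List iter_kmers_cpp(std::string seq, int k) {
  check_k(k);
  KmerCodec cod(k);
  long L = (long)seq.size();
  long n = L - k + 1;
  if (n < 0) n = 0;
  IntegerVector pos((R_xlen_t)n);
  CharacterVector kmer((R_xlen_t)n);
  LogicalVector valid((R_xlen_t)n);
  u128 f = 0, r = 0;
  int run = 0;
  for (long p = 0; p < L; ++p) {
    int b = base_code(seq[(size_t)p]);
    if (b < 0) { run = 0; f = 0; r = 0; } else { cod.roll(b, f, r); ++run; }
    long w = p - k + 1;
    if (w < 0) continue;
    pos[(R_xlen_t)w] = (int)(w + 1);
    if (run >= k) {
      valid[(R_xlen_t)w] = true;
      kmer[(R_xlen_t)w] = decode_kmer(f < r ? f : r, k);
    } else {
      valid[(R_xlen_t)w] = false;
      kmer[(R_xlen_t)w] = NA_STRING;
    }
  }
  return List::create(_["start"] = pos, _["kmer"] = kmer, _["valid"] = valid);
}

static std::string hash_hex(uint64_t h1, uint64_t h2) {
  char buf[36];
  snprintf(buf, sizeof(buf), "%016llx%016llx",
           (unsigned long long)h1, (unsigned long long)h2);
  return std::string(buf);
}

// rolling digests of every valid window (NA where invalid)
// [[Rcpp::export]]
CharacterVector kmer_hashes_rolling(std::string seq, int k) {
  check_k(k);
  KmerCodec cod(k);
  long L = (long)seq.size();
  long n = L - k + 1;
  if (n < 0) n = 0;
  CharacterVector out((R_xlen_t)n);
  u128 f = 0, r = 0;
  int run = 0;
  for (long p = 0; p < L; ++p) {
    int b = base_code(seq[(size_t)p]);
    if (b < 0) { run = 0; f = 0; r = 0; } else { cod.roll(b, f, r); ++run; }
    long w = p - k + 1;
    if (w < 0) continue;
    if (run >= k) {
      uint64_t h1, h2;
      kmer_hash_pair(f < r ? f : r, h1, h2);
      out[(R_xlen_t)w] = hash_hex(h1, h2);
    } else out[(R_xlen_t)w] = NA_STRING;
  }
  return out;
}

// digest of isolated k-mer strings, encoded from scratch (non-rolling path)
// [[Rcpp::export]]
CharacterVector kmer_hashes_direct(CharacterVector kmers, int k) {
  check_k(k);
  KmerCodec cod(k);
  CharacterVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    u128 c;
    if (!encode_kmer(s, cod, c)) { out[i] = NA_STRING; continue; }
    uint64_t h1, h2;
    kmer_hash_pair(c, h1, h2);
    out[i] = hash_hex(h1, h2);
  }
  return out;
}

// ---- Bloom filter ---------------------------------------------------------

// [[Rcpp::export]]
SEXP bf_new(int k, double m, int h, double p_target) {
  check_k(k);
  if (m < 1) stop("bit-array length m must be >= 1");
  if (h < 1) stop("hash count h must be >= 1");
  XPtr<KmerMembership> p(new BloomFilter(k, (uint64_t)m, h, p_target), true);
  return p;
}

static BloomFilter *as_bloom(SEXP ptr) {
  XPtr<KmerMembership> p(ptr);
  BloomFilter *bf = dynamic_cast<BloomFilter *>(p.get());
  if (!bf) stop("not a Bloom filter handle");
  return bf;
}

// [[Rcpp::export]]
void bf_insert(SEXP ptr, CharacterVector kmers) {
  BloomFilter *bf = as_bloom(ptr);
  KmerCodec cod(bf->k);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    u128 c;
    if (!encode_kmer(s, cod, c))
      stop("cannot insert k-mer with non-ACGT characters: '%s'", s.c_str());
    bf->insert_enc(c);
  }
}

// [[Rcpp::export]]
LogicalVector membership_contains(SEXP ptr, CharacterVector kmers) {
  XPtr<KmerMembership> p(ptr);
  KmerCodec cod(p->k);
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    u128 c;
    if (!encode_kmer(s, cod, c)) { out[i] = NA_LOGICAL; continue; }
    out[i] = p->contains_enc(c);
  }
  return out;
}

// [[Rcpp::export]]
int membership_k(SEXP ptr) {
  XPtr<KmerMembership> p(ptr);
  return p->k;
}

// [[Rcpp::export]]
List bf_header(SEXP ptr) {
  BloomFilter *bf = as_bloom(ptr);
  return List::create(_["k"] = bf->k, _["m"] = (double)bf->m, _["h"] = bf->h,
                      _["n_inserted"] = (double)bf->n_inserted,
                      _["p_target"] = bf->p_target);
}

// bit array as raw bytes (little-endian 64-bit words) for serialization
// [[Rcpp::export]]
RawVector bf_bits(SEXP ptr) {
  BloomFilter *bf = as_bloom(ptr);
  RawVector out((R_xlen_t)(bf->words.size() * 8));
  for (size_t i = 0; i < bf->words.size(); ++i) {
    uint64_t w = bf->words[i];
    for (int j = 0; j < 8; ++j) out[(R_xlen_t)(i * 8 + j)] = (Rbyte)((w >> (8 * j)) & 0xFF);
  }
  return out;
}

// [[Rcpp::export]]
SEXP bf_from_bits(int k, double m, int h, double n_inserted, double p_target,
                  RawVector bits) {
  check_k(k);
  BloomFilter *bf = new BloomFilter(k, (uint64_t)m, h, p_target);
  bf->n_inserted = (uint64_t)n_inserted;
  if ((size_t)bits.size() != bf->words.size() * 8) {
    size_t need = bf->words.size() * 8;
    delete bf;
    stop("bit array has %d bytes but m = %.0f requires %d",
         (int)bits.size(), m, (int)need);
  }
  for (size_t i = 0; i < bf->words.size(); ++i) {
    uint64_t w = 0;
    for (int j = 0; j < 8; ++j) w |= ((uint64_t)(Rbyte)bits[(R_xlen_t)(i * 8 + j)]) << (8 * j);
    bf->words[i] = w;
  }
  XPtr<KmerMembership> p(bf, true);
  return p;
}

// ---- exact k-mer set (zero-FPR oracle used in tests and validation) -------

// [[Rcpp::export]]
SEXP exact_set_new(int k) {
  check_k(k);
  XPtr<KmerMembership> p(new ExactKmerSet(k), true);
  return p;
}

static ExactKmerSet *as_exact(SEXP ptr) {
  XPtr<KmerMembership> p(ptr);
  ExactKmerSet *es = dynamic_cast<ExactKmerSet *>(p.get());
  if (!es) stop("not an exact k-mer set handle");
  return es;
}

// [[Rcpp::export]]
void exact_set_insert(SEXP ptr, CharacterVector kmers) {
  ExactKmerSet *es = as_exact(ptr);
  KmerCodec cod(es->k);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    u128 c;
    if (!encode_kmer(s, cod, c))
      stop("cannot insert k-mer with non-ACGT characters: '%s'", s.c_str());
    es->set.insert(c);
  }
}

// add every valid window of each sequence
// [[Rcpp::export]]
void exact_set_add_seq(SEXP ptr, CharacterVector seqs) {
  ExactKmerSet *es = as_exact(ptr);
  KmerCodec cod(es->k);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    u128 f = 0, r = 0;
    int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int b = base_code(s[p]);
      if (b < 0) { run = 0; f = 0; r = 0; continue; }
      cod.roll(b, f, r);
      if (++run >= cod.k) es->set.insert(f < r ? f : r);
    }
  }
}

// [[Rcpp::export]]
double exact_set_size(SEXP ptr) { return (double)as_exact(ptr)->set.size(); }

// ---- random k-mers and the FPR experiment ---------------------------------

static u128 random_kmer_enc(const KmerCodec &cod, u128 &fwd, u128 &rc) {
  fwd = 0; rc = 0;
  for (int j = 0; j < cod.k; ++j) {
    int b = (int)(unif_rand() * 4.0);
    if (b > 3) b = 3;
    cod.roll(b, fwd, rc);
  }
  return fwd < rc ? fwd : rc;
}

// uniformly random k-mer strings (not canonicalized); uses R's RNG
// [[Rcpp::export]]
CharacterVector random_kmers_cpp(int n, int k) {
  check_k(k);
  KmerCodec cod(k);
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    u128 f, r;
    random_kmer_enc(cod, f, r);
    out[i] = decode_kmer(f, k);
  }
  return out;
}

// Insert n_insert random distinct canonical k-mers into a fresh filter of the
// given geometry, then probe with n_probe distinct k-mers disjoint from the
// inserted set; returns the empirical false-positive rate.
// [[Rcpp::export]]
List bloom_fpr_experiment_cpp(int k, double m, int h, double p_target,
                              double n_insert, double n_probe) {
  check_k(k);
  KmerCodec cod(k);
  BloomFilter bf(k, (uint64_t)m, h, p_target);
  std::unordered_set<u128, U128Hash> seen;
  seen.reserve((size_t)(n_insert + n_probe) * 2);
  uint64_t ni = (uint64_t)n_insert, np = (uint64_t)n_probe;
  while (seen.size() < ni) {
    u128 f, r;
    u128 c = random_kmer_enc(cod, f, r);
    if (seen.insert(c).second) bf.insert_enc(c);
  }
  uint64_t fp = 0, probed = 0;
  while (probed < np) {
    u128 f, r;
    u128 c = random_kmer_enc(cod, f, r);
    if (!seen.insert(c).second) continue;
    ++probed;
    if (bf.contains_enc(c)) ++fp;
  }
  return List::create(_["fpr"] = (double)fp / (double)np,
                      _["n_false_positive"] = (double)fp,
                      _["n_probed"] = (double)np,
                      _["n_inserted"] = (double)bf.n_inserted);
}
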