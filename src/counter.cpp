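#include "kmer_core.h"
using namespace Rcpp;

static KmerCountStore *as_store(SEXP ptr) {
  XPtr<KmerCountStore> p(ptr);
  return p.get();
}

// [[Rcpp::export]]
SEXP kcs_new(int k) {
  check_k(k);
  XPtr<KmerCountStore> p(new KmerCountStore(k), true);
  return p;
}

// count every valid canonical window of every read (rolling)
// [[Rcpp::export]]
void kcs_add(SEXP ptr, CharacterVector reads) {
  KmerCountStore *st = as_store(ptr);
  KmerCodec cod(st->k);
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    u128 f = 0, r = 0;
    int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int b = base_code(s[p]);
      if (b < 0) { run = 0; f = 0; r = 0; continue; }
      cod.roll(b, f, r);
      if (++run >= cod.k) ++st->counts[f < r ? f : r];
    }
  }
}

// [[Rcpp::export]]
int kcs_k(SEXP ptr) { return as_store(ptr)->k; }

// [[Rcpp::export]]
double kcs_n_distinct(SEXP ptr) { return (double)as_store(ptr)->counts.size(); }

// multiplicity histogram: how many distinct k-mers occur each number of times
// [[Rcpp::export]]
DataFrame kcs_histogram(SEXP ptr) {
  KmerCountStore *st = as_store(ptr);
  std::unordered_map<uint32_t, double> hist;
  for (const auto &kv : st->counts) hist[kv.second] += 1.0;
  std::vector<uint32_t> mult;
  mult.reserve(hist.size());
  for (const auto &kv : hist) mult.push_back(kv.first);
  std::sort(mult.begin(), mult.end());
  IntegerVector m((R_xlen_t)mult.size());
  NumericVector n((R_xlen_t)mult.size());
  for (size_t i = 0; i < mult.size(); ++i) {
    m[(R_xlen_t)i] = (int)mult[i];
    n[(R_xlen_t)i] = hist[mult[i]];
  }
  return DataFrame::create(_["multiplicity"] = m, _["n_kmers"] = n);
}

// [[Rcpp::export]]
IntegerVector kcs_lookup(SEXP ptr, CharacterVector kmers) {
  KmerCountStore *st = as_store(ptr);
  KmerCodec cod(st->k);
  IntegerVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    u128 c;
    if (!encode_kmer(s, cod, c)) { out[i] = NA_INTEGER; continue; }
    auto it = st->counts.find(c);
    out[i] = (it == st->counts.end()) ? 0 : (int)it->second;
  }
  return out;
}

// [[Rcpp::export]]
double kcs_n_solid(SEXP ptr, int c_min) {
  KmerCountStore *st = as_store(ptr);
  double n = 0;
  for (const auto &kv : st->counts)
    if ((int)kv.second >= c_min) n += 1.0;
  return n;
}

// insert every k-mer with multiplicity >= c_min into a Bloom filter or exact set
// [[Rcpp::export]]
double kcs_fill_membership(SEXP ptr, SEXP memb, int c_min) {
  KmerCountStore *st = as_store(ptr);
  XPtr<KmerMembership> mp(memb);
  if (mp->k != st->k)
    stop("k mismatch: count store has k = %d, filter has k = %d", st->k, mp->k);
  BloomFilter *bf = dynamic_cast<BloomFilter *>(mp.get());
  ExactKmerSet *es = dynamic_cast<ExactKmerSet *>(mp.get());
  double n = 0;
  for (const auto &kv : st->counts) {
    if ((int)kv.second < c_min) continue;
    if (bf) bf->insert_enc(kv.first);
    else if (es) es->set.insert(kv.first);
    else stop("unknown membership structure");
    n += 1.0;
  }
  return n;
}

// per-read substitution errors at a fixed per-base rate (Illumina-like);
// draws come from R's RNG so results follow set.seed()
// [[Rcpp::export]]
CharacterVector inject_substitutions_cpp(CharacterVector reads, double rate) {
  if (rate < 0 || rate > 1) stop("error rate must be in [0, 1]");
  CharacterVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    for (size_t p = 0; p < s.size(); ++p) {
      if (unif_rand() >= rate) continue;
      int b = base_code(s[p]);
      if (b < 0) continue;
      int shift = 1 + (int)(unif_rand() * 3.0);
      if (shift > 3) shift = 3;
      s[p] = code_base((b + shift) & 3);
    }
    out[i] = s;
  }
  return out;
}
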