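#include "kmer_core.h"
using namespace Rcpp;

// Leniency thresholds are ceil(k/x) and ceil(k/y) over the k overlapping
// windows; near contig ends (or next to non-ACGT runs) they are computed on
// the windows actually available.
static int leniency_threshold(int n_avail, int k, double divisor) {
  int a = n_avail < k ? n_avail : k;
  int t = (int)std::ceil((double)a / divisor);
  return t < 1 ? 1 : t;
}

// count absent / valid windows among the k windows covering base i
static void assess_at(const std::string &s, long i, const KmerCodec &cod,
                      const KmerMembership &bf, int &n_missing, int &n_valid) {
  n_missing = 0;
  n_valid = 0;
  long L = (long)s.size();
  long lo = i - cod.k + 1;
  if (lo < 0) lo = 0;
  long hi = i;
  if (hi > L - cod.k) hi = L - cod.k;
  for (long w = lo; w <= hi; ++w) {
    u128 c;
    if (!cod.window(s, (size_t)w, c)) continue;
    ++n_valid;
    if (!bf.contains_enc(c)) ++n_missing;
  }
}

// Support for a candidate edit at base i: replace del_len original bases by
// `repl` and count present windows among those containing the ENTIRE change
// (for a deletion, those straddling the junction). Requiring full containment
// matters: counting windows that merely end inside an insertion would credit
// partial copies of nearby genomic sequence and let the scan insert its way
// along the genome indefinitely. `anchored_present` reports whether the
// left-anchored window (the one ending at the last replacement base, with no
// 3' context) is present; the insertion beam search extends prefixes on it.
static void cand_support(const std::string &s, long i, const std::string &repl,
                         long del_len, const KmerCodec &cod,
                         const KmerMembership &bf, int &support, int &n_valid,
                         bool &anchored_present) {
  support = 0;
  n_valid = 0;
  anchored_present = true;  // stays true when the anchored window is clipped off
  long L = (long)s.size();
  int k = cod.k;
  long rlen = (long)repl.size();
  long left_lo = i - (k - 1);
  if (left_lo < 0) left_lo = 0;
  std::string local = s.substr((size_t)left_lo, (size_t)(i - left_lo));
  long q0 = (long)local.size();  // local coordinate of the change
  local += repl;
  long rs = i + del_len;
  long rn = L - rs;
  if (rn > k - 1) rn = k - 1;
  if (rn > 0) local += s.substr((size_t)rs, (size_t)rn);
  long lo, hi;
  if (rlen > 0) {        // substitution / insertion: windows containing all
    lo = q0 + rlen - k;  // replacement bases
    hi = q0;
  } else {               // deletion: windows straddling the junction
    lo = q0 - (k - 1);
    hi = q0 - 1;
  }
  long anchored = lo;
  if (lo < 0) lo = 0;
  long wmax = (long)local.size() - k;
  if (hi > wmax) hi = wmax;
  for (long w = lo; w <= hi; ++w) {
    u128 c;
    if (!cod.window(local, (size_t)w, c)) continue;
    ++n_valid;
    bool present = bf.contains_enc(c);
    if (present) ++support;
    if (rlen > 0 && w == anchored) anchored_present = present;
  }
}

enum EditKind { KIND_SUB = 0, KIND_DEL = 1, KIND_INS = 2 };

struct Candidate {
  int kind;
  std::string bases;  // sub: alt base; del: deleted bases; ins: inserted bases
  int support;
};

// deterministic preference: support desc, shorter edit, deletion before
// insertion, then lexicographic bases
static bool better_than(const Candidate &a, const Candidate &b) {
  if (a.support != b.support) return a.support > b.support;
  if (a.bases.size() != b.bases.size()) return a.bases.size() < b.bases.size();
  if (a.kind != b.kind) return a.kind < b.kind;
  return a.bases < b.bases;
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// all qualifying substitutions at base i, in preference order
static std::vector<Candidate> gather_substitutions(const std::string &s, long i,
                                                   const KmerCodec &cod,
                                                   const KmerMembership &bf,
                                                   double y) {
  std::vector<Candidate> out;
  char orig = s[(size_t)i];
  for (int bi = 0; bi < 4; ++bi) {
    char b = BASES[bi];
    if (b == orig) continue;
    int sup, nv;
    bool anch;
    cand_support(s, i, std::string(1, b), 1, cod, bf, sup, nv, anch);
    if (nv == 0) continue;
    if (sup < leniency_threshold(nv, cod.k, y)) continue;
    out.push_back(Candidate{KIND_SUB, std::string(1, b), sup});
  }
  std::sort(out.begin(), out.end(), better_than);
  return out;
}

// best qualifying micro-indel at base i (deletions of 1..max_indel original
// bases, then insertions of up to max_indel bases before i), or found = false.
// Insertion strings of length 1-2 are fully enumerated; longer ones extend a
// prefix only when its left-anchored window is present in the filter, which
// keeps the search bounded without dropping true candidates (every prefix of
// a correct insertion has a filter-present anchored window).
static std::vector<Candidate> gather_indels(const std::string &s, long i,
                                            const KmerCodec &cod,
                                            const KmerMembership &bf, double y,
                                            int max_indel) {
  std::vector<Candidate> out;
  long L = (long)s.size();
  for (int d = 1; d <= max_indel && i + d <= L; ++d) {
    int sup, nv;
    bool anch;
    cand_support(s, i, "", d, cod, bf, sup, nv, anch);
    if (nv == 0) continue;
    if (sup < leniency_threshold(nv, cod.k, y)) continue;
    out.push_back(Candidate{KIND_DEL, s.substr((size_t)i, (size_t)d), sup});
  }
  std::vector<std::string> level(1, "");
  for (int len = 1; len <= max_indel; ++len) {
    std::vector<std::string> next;
    for (const std::string &pre : level) {
      for (int bi = 0; bi < 4; ++bi) {
        std::string cand = pre + BASES[bi];
        int sup, nv;
        bool anch;
        cand_support(s, i, cand, 0, cod, bf, sup, nv, anch);
        if (nv > 0 && sup >= leniency_threshold(nv, cod.k, y))
          out.push_back(Candidate{KIND_INS, cand, sup});
        if (len < 2 || anch) next.push_back(cand);
      }
    }
    level.swap(next);
    if (level.empty()) break;
  }
  std::sort(out.begin(), out.end(), better_than);
  return out;
}

// Post-edit verification: a correct repair turns every window covering the
// edited site back into a genomic k-mer, so after tentatively applying a
// change the site must no longer trigger the first leniency test. Without
// this check a partially-matching change (e.g. extending a homopolymer one
// base at a time at an unrepairable junction) can be accepted over and over
// on the strength of windows that match elsewhere in the genome.
static bool site_repaired(const std::string &s, long i, long change_len,
                          const KmerCodec &cod, const KmerMembership &bf,
                          double x) {
  long L = (long)s.size();
  int k = cod.k;
  long lo = i - (k - 1);
  if (lo < 0) lo = 0;
  long hi = i + change_len - 1;
  if (hi < lo) hi = lo;
  if (hi > L - k) hi = L - k;
  int n_missing = 0, n_valid = 0;
  for (long w = lo; w <= hi; ++w) {
    u128 c;
    if (!cod.window(s, (size_t)w, c)) continue;
    ++n_valid;
    if (!bf.contains_enc(c)) ++n_missing;
  }
  if (n_valid == 0) return false;
  return n_missing < leniency_threshold(n_valid, k, x);
}

// ---- exported single-position probes (used by unit tests and power users) --

// [[Rcpp::export]]
List assess_position_cpp(std::string seq, double i0, SEXP memb) {
  XPtr<KmerMembership> bf(memb);
  KmerCodec cod(bf->k);
  long i = (long)i0;
  if (i < 0 || i >= (long)seq.size()) stop("position out of range");
  int n_missing, n_valid;
  assess_at(seq, i, cod, *bf, n_missing, n_valid);
  return List::create(_["n_missing"] = n_missing, _["n_valid"] = n_valid);
}

// [[Rcpp::export]]
List try_substitutions_cpp(std::string seq, double i0, SEXP memb, double y) {
  XPtr<KmerMembership> bf(memb);
  KmerCodec cod(bf->k);
  long i = (long)i0;
  if (i < 0 || i >= (long)seq.size()) stop("position out of range");
  std::vector<Candidate> cands = gather_substitutions(seq, i, cod, *bf, y);
  if (cands.empty()) return List::create(_["found"] = false);
  return List::create(_["found"] = true, _["alt"] = cands[0].bases,
                      _["n_support"] = cands[0].support);
}

// [[Rcpp::export]]
List try_indels_cpp(std::string seq, double i0, SEXP memb, double y,
                    int max_indel) {
  XPtr<KmerMembership> bf(memb);
  KmerCodec cod(bf->k);
  long i = (long)i0;
  if (i < 0 || i >= (long)seq.size()) stop("position out of range");
  std::vector<Candidate> cands = gather_indels(seq, i, cod, *bf, y, max_indel);
  if (cands.empty()) return List::create(_["found"] = false);
  return List::create(
      _["found"] = true,
      _["kind"] = std::string(cands[0].kind == KIND_DEL ? "deletion" : "insertion"),
      _["bases"] = cands[0].bases, _["n_support"] = cands[0].support);
}

// ---- full contig scan -----------------------------------------------------

// Single 5'->3' pass. Each absent k-mer puts its 3'-end base under scrutiny;
// when enough covering windows are absent (first leniency factor) the base is
// permuted and then probed for micro-indels, and the best change with enough
// present windows (second leniency factor) is applied. The scan resumes on
// the edited sequence at the base following the change. Reported positions
// are 1-based on the ORIGINAL input sequence.
// [[Rcpp::export]]
List polish_contig_cpp(std::string seq, SEXP memb, double x, double y,
                       int max_indel, bool do_indels) {
  XPtr<KmerMembership> bf(memb);
  int k = bf->k;
  KmerCodec cod(k);
  for (size_t j = 0; j < seq.size(); ++j) seq[j] = (char)toupper(seq[j]);

  std::vector<double> r_pos;
  std::vector<std::string> r_kind, r_ref, r_alt;
  std::vector<int> r_missing, r_support;

  long offset = 0;  // current coordinate minus original coordinate
  long orig_len = (long)seq.size();
  long w = 0;
  long iter = 0;
  while (w + k <= (long)seq.size()) {
    if ((++iter & 0xFFF) == 0) Rcpp::checkUserInterrupt();
    u128 c;
    bool valid = cod.window(seq, (size_t)w, c);
    if (!valid || bf->contains_enc(c)) { ++w; continue; }
    long i = w + k - 1;  // scrutinized 3'-end base
    int n_missing, n_avail;
    assess_at(seq, i, cod, *bf, n_missing, n_avail);
    if (n_avail == 0 || n_missing < leniency_threshold(n_avail, k, x)) {
      ++w;
      continue;
    }
    // candidates in precedence order: substitutions, then indels; each is
    // applied tentatively and kept only when the site verifies as repaired
    // (the process repeats until a change with sufficient support is made or
    // all possible edits at the position are exhausted)
    std::vector<Candidate> cands = gather_substitutions(seq, i, cod, *bf, y);
    if (do_indels) {
      std::vector<Candidate> ind = gather_indels(seq, i, cod, *bf, y, max_indel);
      cands.insert(cands.end(), ind.begin(), ind.end());
    }
    double orig_pos = (double)(i - offset + 1);  // 1-based, original coords
    long resume = -1;                            // first base after the change
    for (const Candidate &cn : cands) {
      if (cn.kind == KIND_SUB) {
        char saved = seq[(size_t)i];
        seq[(size_t)i] = cn.bases[0];
        if (!site_repaired(seq, i, 1, cod, *bf, x)) {
          seq[(size_t)i] = saved;
          continue;
        }
        r_kind.push_back("substitution");
        r_ref.push_back(std::string(1, saved));
        r_alt.push_back(cn.bases);
        resume = i + 1;
      } else if (cn.kind == KIND_DEL) {
        seq.erase((size_t)i, cn.bases.size());
        if (!site_repaired(seq, i, 0, cod, *bf, x)) {
          seq.insert((size_t)i, cn.bases);
          continue;
        }
        r_kind.push_back("deletion");
        r_ref.push_back(cn.bases);
        r_alt.push_back("");
        offset -= (long)cn.bases.size();
        resume = i;
      } else {
        seq.insert((size_t)i, cn.bases);
        if (!site_repaired(seq, i, (long)cn.bases.size(), cod, *bf, x)) {
          seq.erase((size_t)i, cn.bases.size());
          continue;
        }
        r_kind.push_back("insertion");
        r_ref.push_back("");
        r_alt.push_back(cn.bases);
        offset += (long)cn.bases.size();
        resume = i + (long)cn.bases.size();
      }
      r_pos.push_back(orig_pos);
      r_missing.push_back(n_missing);
      r_support.push_back(cn.support);
      break;
    }
    if (resume < 0) { ++w; continue; }  // nothing qualified and verified
    w = resume - (k - 1);
    if (w < 0) w = 0;
    if ((long)seq.size() > 2 * orig_len + 1024) {
      Rcpp::warning("polishing aborted: edited sequence grew to twice the "
                    "input length, which indicates a degenerate filter");
      break;
    }
  }

  DataFrame edits = DataFrame::create(
      _["position"] = wrap(r_pos), _["kind"] = wrap(r_kind),
      _["ref"] = wrap(r_ref), _["alt"] = wrap(r_alt),
      _["n_missing"] = wrap(r_missing), _["n_support"] = wrap(r_support),
      _["stringsAsFactors"] = false);
  return List::create(_["seq"] = seq, _["edits"] = edits);
}
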