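#' Canonical form of a k-mer
#'
#' Returns the lexicographically smaller of each word and its reverse
#' complement, the strand-independent representation under which all k-mers
#' are counted, stored and queried. Input is uppercased first; the operation
#' is an involution (`canonical_kmer(canonical_kmer(x)) == canonical_kmer(x)`).
#'
#' @param x character vector of DNA words (A/C/G/T only).
#' @return character vector of canonical words.
#' @examples
#' canonical_kmer(c("TTTT", "GATTACA"))
#' @export
canonical_kmer <- function(x) {
  canonical_cpp(as.character(x))
}

#' Enumerate the k-mer windows of a sequence
#'
#' Yields one row per window start (1-based), in 5'->3' order. Windows that
#' overlap any non-ACGT character are flagged invalid with `kmer = NA`: they
#' carry no presence/absence evidence and are never inserted into a filter.
#' Sequences shorter than `k` give zero rows.
#'
#' @param seq a single DNA sequence (character scalar or [Biostrings::DNAString]).
#' @param k word length, 4-64.
#' @return data.frame with columns `start`, `kmer` (canonical), `valid`.
#' @export
kmer_windows <- function(seq, k) {
  seq <- as_seq_string(seq)
  res <- iter_kmers_cpp(seq, as.integer(k))
  data.frame(start = res$start, kmer = res$kmer, valid = res$valid,
             stringsAsFactors = FALSE)
}

#' Bloom filter geometry for a target false-positive rate
#'
#' Standard sizing: `m = ceiling(-n * log(p) / log(2)^2)` bits and
#' `h = max(1, round(m / n * log(2)))` hash functions, the geometry that
#' minimizes the false-positive rate at a given bits-per-element budget.
#'
#' @param n_expected expected number of distinct k-mers to be inserted.
#' @param p_target design false-positive rate, in (0, 1). Default 0.0005,
#'   low enough that spurious presence calls do not disturb editing.
#' @return list with elements `m` (bits) and `h` (hash count).
#' @examples
#' bloom_dimensions(1e6, 0.0005)
#' @export
bloom_dimensions <- function(n_expected, p_target = 0.0005) {
  if (n_expected < 1) stop("n_expected must be >= 1")
  if (!is.numeric(p_target) || p_target <= 0 || p_target >= 1)
    stop("p_target must be strictly between 0 and 1")
  m <- ceiling(-n_expected * log(p_target) / log(2)^2)
  h <- max(1, round(m / n_expected * log(2)))
  list(m = m, h = as.integer(h))
}

#' Create an empty canonical k-mer Bloom filter
#'
#' The filter stores canonical k-mers only, so queries are strand-symmetric,
#' and it never returns a false negative. Geometry is taken from
#' [bloom_dimensions()] unless `m` and `h` are given explicitly.
#'
#' The handle has reference semantics: [kmer_insert()] modifies it in place.
#'
#' @param k k-mer length, 4-64.
#' @param n_expected expected number of distinct insertions (used for sizing).
#' @param p_target design false-positive rate.
#' @param m,h explicit geometry overriding the sizing rule (both or neither).
#' @return an object of class `kmer_bloom`.
#' @export
kmer_bloom <- function(k, n_expected, p_target = 0.0005, m = NULL, h = NULL) {
  k <- as.integer(k)
  if (is.null(m) != is.null(h)) stop("give both m and h, or neither")
  if (is.null(m)) {
    dims <- bloom_dimensions(n_expected, p_target)
    m <- dims$m
    h <- dims$h
  }
  structure(
    list(ptr = bf_new(k, as.numeric(m), as.integer(h), p_target),
         k = k, m = as.numeric(m), h = as.integer(h), p_target = p_target),
    class = c("kmer_bloom", "kmer_filter")
  )
}

#' Exact canonical k-mer set
#'
#' A hash-set membership structure with the same query interface as
#' [kmer_bloom()] but a zero false-positive rate. It is the oracle against
#' which the Bloom-filter pipeline is validated, and is practical for small
#' genomes.
#'
#' @param k k-mer length, 4-64.
#' @param kmers optional character vector of k-mers to insert.
#' @return an object of class `kmer_exact_set`.
#' @export
exact_kmer_set <- function(k, kmers = NULL) {
  k <- as.integer(k)
  obj <- structure(list(ptr = exact_set_new(k), k = k),
                   class = c("kmer_exact_set", "kmer_filter"))
  if (!is.null(kmers)) exact_set_insert(obj$ptr, as.character(kmers))
  obj
}

#' Exact k-mer set of one or more sequences
#'
#' Collects every valid canonical k-mer of the given sequences into an
#' [exact_kmer_set()]. With the truth genome as input this is the ideal,
#' error-free filter used by the editor's oracle tests.
#'
#' @param seqs character vector or [Biostrings::DNAStringSet].
#' @param k k-mer length.
#' @return an object of class `kmer_exact_set`.
#' @export
genome_kmer_set <- function(seqs, k) {
  obj <- exact_kmer_set(k)
  exact_set_add_seq(obj$ptr, as_seq_strings(seqs))
  obj
}

#' Insert k-mers into a filter
#'
#' K-mers are canonicalized before insertion. The filter is modified in place
#' (reference semantics); the handle is returned invisibly for chaining.
#'
#' @param filter a `kmer_bloom` or `kmer_exact_set`.
#' @param kmers character vector of k-mers of length `filter$k`.
#' @return the filter, invisibly.
#' @export
kmer_insert <- function(filter, kmers) {
  stopifnot(inherits(filter, "kmer_filter"))
  if (inherits(filter, "kmer_bloom")) bf_insert(filter$ptr, as.character(kmers))
  else exact_set_insert(filter$ptr, as.character(kmers))
  invisible(filter)
}

#' Query a filter for k-mer presence
#'
#' Queries are canonicalized first, so `kmer_contains(f, s)` equals
#' `kmer_contains(f, reverseComplement(s))` for every k-mer `s`. Inserted
#' k-mers always return `TRUE`; never-inserted k-mers return `TRUE` with
#' probability about `p_target` for a Bloom filter and never for an exact set.
#' K-mers containing non-ACGT characters return `NA`.
#'
#' @inheritParams kmer_insert
#' @return logical vector.
#' @export
kmer_contains <- function(filter, kmers) {
  stopifnot(inherits(filter, "kmer_filter"))
  membership_contains(filter$ptr, as.character(kmers))
}

#' Filter header fields
#'
#' @param filter a `kmer_bloom` or `kmer_exact_set`.
#' @return list with `k`, and for Bloom filters `m`, `h`, `n_inserted`,
#'   `p_target`; for exact sets `n_inserted` only.
#' @export
filter_info <- function(filter) {
  stopifnot(inherits(filter, "kmer_filter"))
  if (inherits(filter, "kmer_bloom")) bf_header(filter$ptr)
  else list(k = filter$k, n_inserted = exact_set_size(filter$ptr))
}

#' @export
print.kmer_bloom <- function(x, ...) {
  hd <- bf_header(x$ptr)
  cat(sprintf(
    "canonical k-mer Bloom filter: k=%d, m=%.0f bits (%.1f MB), h=%d, n_inserted=%.0f, target FPR=%g\n",
    hd$k, hd$m, hd$m / 8 / 2^20, hd$h, hd$n_inserted, hd$p_target))
  invisible(x)
}

#' @export
print.kmer_exact_set <- function(x, ...) {
  cat(sprintf("exact canonical k-mer set: k=%d, n=%.0f k-mers\n",
              x$k, exact_set_size(x$ptr)))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

BLOOM_MAGIC <- charToRaw("KPBLOOM1")
BLOOM_FORMAT_VERSION <- 1L

#' Write a Bloom filter to a binary file
#'
#' Byte layout (little-endian): 8-byte magic `"KPBLOOM1"`; int32 format
#' version; int32 `k`; double `m` (bits); int32 `h`; double `n_inserted`;
#' double `p_target`; double byte-count of the bit array; then the bit array
#' as 64-bit words. [load_kmer_bloom()] restores a filter whose queries are
#' bit-for-bit identical.
#'
#' @param filter a `kmer_bloom`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_kmer_bloom <- function(filter, path) {
  stopifnot(inherits(filter, "kmer_bloom"))
  hd <- bf_header(filter$ptr)
  bits <- bf_bits(filter$ptr)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(BLOOM_MAGIC, con)
  writeBin(as.integer(c(BLOOM_FORMAT_VERSION, hd$k)), con, size = 4L,
           endian = "little")
  writeBin(as.numeric(hd$m), con, endian = "little")
  writeBin(as.integer(hd$h), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(hd$n_inserted, hd$p_target, length(bits))), con,
           endian = "little")
  writeBin(bits, con)
  invisible(path)
}

#' Read a Bloom filter written by [save_kmer_bloom()]
#'
#' @param path file produced by [save_kmer_bloom()].
#' @param k if given, the k the caller intends to edit with; a mismatch with
#'   the stored k is an error (editor and filter must share k).
#' @return a `kmer_bloom`.
#' @export
load_kmer_bloom <- function(path, k = NULL) {
  if (!file.exists(path)) stop("no such filter file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  if (length(magic) < 8L || !identical(magic, BLOOM_MAGIC))
    stop("bad magic bytes: '", path, "' is not a kmerpolish Bloom filter file")
  ints <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  if (length(ints) < 2L) stop("truncated filter file (header version/k): ", path)
  if (ints[1] != BLOOM_FORMAT_VERSION)
    stop("unsupported filter format version ", ints[1])
  k_stored <- ints[2]
  m <- readBin(con, "numeric", n = 1L, endian = "little")
  h <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  nums <- readBin(con, "numeric", n = 3L, endian = "little")
  if (length(m) < 1L || length(h) < 1L || length(nums) < 3L)
    stop("truncated filter file (header m/h/n_inserted/p_target): ", path)
  n_bytes <- nums[3]
  bits <- readBin(con, "raw", n = n_bytes)
  if (length(bits) < n_bytes)
    stop("truncated filter file (bit array): expected ", n_bytes,
         " bytes, got ", length(bits))
  if (!is.null(k) && as.integer(k) != k_stored)
    stop("k mismatch: filter file has k = ", k_stored,
         " but k = ", k, " was requested")
  structure(
    list(ptr = bf_from_bits(k_stored, m, h, nums[1], nums[2], bits),
         k = k_stored, m = m, h = as.integer(h), p_target = nums[2]),
    class = c("kmer_bloom", "kmer_filter")
  )
}

#' Empirical false-positive rate of a Bloom filter geometry
#'
#' Builds a fresh filter for `n_insert` expected k-mers, inserts that many
#' random distinct canonical k-mers, then probes it with `n_probe` distinct
#' k-mers disjoint from the inserted set. With the default sizing rule the
#' returned rate should sit near `p_target`. Randomness follows R's RNG, so
#' results are reproducible under [set.seed()].
#'
#' @param n_insert,n_probe numbers of inserted and probed distinct k-mers.
#' @param k k-mer length.
#' @param p_target design false-positive rate used for sizing.
#' @return list with `fpr`, `n_false_positive`, `n_probed`, `m`, `h`.
#' @export
bloom_fpr_experiment <- function(n_insert, n_probe, k = 25, p_target = 0.0005) {
  dims <- bloom_dimensions(n_insert, p_target)
  res <- bloom_fpr_experiment_cpp(as.integer(k), dims$m, dims$h, p_target,
                                  n_insert, n_probe)
  res$m <- dims$m
  res$h <- dims$h
  res
}

# ---- internal coercions ----------------------------------------------------

as_seq_string <- function(x) {
  if (methods::is(x, "XString") || methods::is(x, "XStringSet")) {
    x <- as.character(x)
  }
  if (length(x) != 1L) stop("expected a single sequence")
  toupper(unname(x))
}

as_seq_strings <- function(x) {
  if (methods::is(x, "XStringSet") || methods::is(x, "XString")) {
    out <- as.character(x)
  } else {
    nm <- names(x)
    out <- as.character(x)  # as.character() drops names; restore them
    names(out) <- nm
  }
  toupper(out)
}
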