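#' Count canonical k-mers in a set of reads
#'
#' Streams every read once and counts each valid canonical k-mer occurrence
#' exactly (hash-map counting; windows overlapping non-ACGT characters are
#' skipped). Qualities and pairing are ignored: a read is just a sequence.
#'
#' @param reads character vector, [Biostrings::DNAStringSet], or a vector of
#'   FASTA/FASTQ file paths (gzip transparent).
#' @param k k-mer length, 4-64.
#' @return an object of class `kmer_counts` (a handle with reference
#'   semantics; see [kmer_histogram()], [kmer_multiplicity()]).
#' @export
count_kmers <- function(reads, k) {
  st <- structure(list(ptr = kcs_new(as.integer(k)), k = as.integer(k)),
                  class = "kmer_counts")
  add_reads(st, reads)
  if (kcs_n_distinct(st$ptr) == 0)
    warning("no valid k-mers found in the input reads")
  st
}

add_reads <- function(store, reads) {
  if (is.character(reads) && length(reads) > 0 && all(file.exists(reads))) {
    for (f in reads) kcs_add(store$ptr, as_seq_strings(read_fastx(f)))
  } else {
    kcs_add(store$ptr, as_seq_strings(reads))
  }
  invisible(store)
}

#' Multiplicity histogram of a k-mer count store
#'
#' @param counts a `kmer_counts` object from [count_kmers()].
#' @return data.frame with columns `multiplicity` and `n_kmers` (number of
#'   distinct k-mers seen exactly that many times); rows sorted by
#'   multiplicity, absent multiplicities omitted.
#' @export
kmer_histogram <- function(counts) {
  stopifnot(inherits(counts, "kmer_counts"))
  kcs_histogram(counts$ptr)
}

#' Multiplicities of specific k-mers
#'
#' @param counts a `kmer_counts` object.
#' @param kmers character vector of k-mers (canonicalized before lookup).
#' @return integer vector of counts (0 for unseen, NA for non-ACGT words).
#' @export
kmer_multiplicity <- function(counts, kmers) {
  stopifnot(inherits(counts, "kmer_counts"))
  kcs_lookup(counts$ptr, as.character(kmers))
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("k-mer count store: k=%d, %.0f distinct canonical k-mers\n",
              x$k, kcs_n_distinct(x$ptr)))
  invisible(x)
}

#' Pick a solid-k-mer coverage threshold from a multiplicity histogram
#'
#' Sequencing-error k-mers pile up at low multiplicities while genomic k-mers
#' cluster near the read coverage, so the histogram is bimodal and the valley
#' between the two modes separates noise from signal. This rule returns the
#' multiplicity of the first minimum between the error mode and the coverage
#' peak (the smallest multiplicity `>= 2` minimizing `n_kmers` up to the
#' peak). When the histogram has no interior valley (e.g. error-free reads or
#' monotone decay) it falls back to `c_min = 2` with a warning. The released
#' k-mer counting tools do not publish their threshold rule; this one is our
#' own and is deliberately simple.
#'
#' @param hist data.frame from [kmer_histogram()].
#' @return integer threshold `c_min >= 2`.
#' @export
select_threshold <- function(hist) {
  stopifnot(is.data.frame(hist), all(c("multiplicity", "n_kmers") %in% names(hist)))
  if (nrow(hist) == 0) stop("empty histogram")
  if (any(hist$multiplicity < 1)) stop("multiplicities must be >= 1")
  max_mult <- max(hist$multiplicity)
  if (max_mult >= 3) {
    counts <- numeric(max_mult)
    counts[hist$multiplicity] <- hist$n_kmers
    # first local minimum: non-increasing from the left, strictly rising after
    for (t in 2:(max_mult - 1)) {
      if (counts[t] <= counts[t - 1] && counts[t] < counts[t + 1])
        return(as.integer(t))
    }
  }
  warning("no interior minimum in k-mer histogram; falling back to c_min = 2")
  2L
}

#' Build a coverage-thresholded canonical k-mer Bloom filter from reads
#'
#' The read-processing half of the polishing pipeline: count canonical
#' k-mers, drop those below the coverage threshold (error k-mers), size a
#' Bloom filter for the surviving ("solid") set at the target false-positive
#' rate, and populate it.
#'
#' @param reads character vector, [Biostrings::DNAStringSet], or FASTA/FASTQ
#'   file path(s) (gzip transparent).
#' @param k k-mer length, 4-64.
#' @param c_min minimum multiplicity for a k-mer to be kept, or `"auto"` to
#'   pick the histogram valley via [select_threshold()]. `c_min = 1` disables
#'   error-k-mer removal.
#' @param p_target Bloom filter design false-positive rate (default 0.0005).
#' @param counts optionally, a precomputed `kmer_counts` store for these
#'   reads (then `reads` may be missing).
#' @param verbose print a build summary.
#' @return a `kmer_bloom` with attributes `c_min`, `n_distinct`, `n_solid`.
#' @export
build_filter <- function(reads, k, c_min = "auto", p_target = 0.0005,
                         counts = NULL, verbose = TRUE) {
  if (is.null(counts)) counts <- count_kmers(reads, k)
  stopifnot(inherits(counts, "kmer_counts"))
  k <- counts$k
  if (identical(c_min, "auto")) {
    c_min <- select_threshold(kmer_histogram(counts))
  } else {
    c_min <- as.integer(c_min)
    if (c_min < 1) stop("c_min must be >= 1")
  }
  n_distinct <- kcs_n_distinct(counts$ptr)
  n_solid <- kcs_n_solid(counts$ptr, c_min)
  if (n_solid == 0)
    stop("no k-mers reach multiplicity ", c_min,
         "; lower c_min or provide reads with more coverage")
  bf <- kmer_bloom(k, n_expected = n_solid, p_target = p_target)
  kcs_fill_membership(counts$ptr, bf$ptr, c_min)
  if (verbose) {
    hd <- bf_header(bf$ptr)
    message(sprintf(
      "build_filter: k=%d, %.0f distinct k-mers seen, c_min=%d, %.0f solid k-mers inserted, m=%.0f bits, h=%d",
      k, n_distinct, c_min, n_solid, hd$m, hd$h))
  }
  structure_add(bf, c_min = c_min, n_distinct = n_distinct, n_solid = n_solid)
}

structure_add <- function(x, ...) {
  extra <- list(...)
  for (nm in names(extra)) attr(x, nm) <- extra[[nm]]
  x
}
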