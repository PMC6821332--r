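#' Editing parameters for the polishing scan
#'
#' Two leniency factors govern the scan. An edit is *attempted* at a base only
#' when at least `ceiling(k / x)` of the k overlapping k-mers covering it are
#' absent from the filter; a candidate change is *accepted* only when at least
#' `ceiling(k / y)` of the overlapping k-mers containing the change are
#' present. Near contig ends (or next to non-ACGT runs) both thresholds are
#' computed on the windows actually available. Larger `x` means fewer
#' attempts; larger `y` means stricter acceptance.
#'
#' @param x missing-k-mer leniency divisor (default 5).
#' @param y present-k-mer leniency divisor (default 9).
#' @param max_indel largest insertion/deletion length tried, 1-5 (default 5).
#' @param mode `"subs+indels"` (default) or `"substitutions-only"`.
#' @return list of class `polish_config`.
#' @export
polish_config <- function(x = 5, y = 9, max_indel = 5,
                          mode = c("subs+indels", "substitutions-only")) {
  mode <- match.arg(mode)
  if (!is.numeric(x) || x < 1) stop("x must be >= 1")
  if (!is.numeric(y) || y < 1) stop("y must be >= 1")
  max_indel <- as.integer(max_indel)
  if (max_indel < 1 || max_indel > 5)
    stop("max_indel must be between 1 and 5")
  structure(list(x = as.numeric(x), y = as.numeric(y), max_indel = max_indel,
                 mode = mode),
            class = "polish_config")
}

#' Count absent k-mers covering a base
#'
#' Interrogates the filter with the (up to) k windows covering the base at
#' `pos`; windows that run off the contig or overlap non-ACGT characters are
#' excluded from both numerator and denominator.
#'
#' @param seq a single DNA sequence.
#' @param pos 1-based position of the scrutinized base.
#' @param filter a `kmer_bloom` or `kmer_exact_set`.
#' @return list with `n_missing` and `n_valid` (available windows).
#' @export
assess_position <- function(seq, pos, filter) {
  stopifnot(inherits(filter, "kmer_filter"))
  assess_position_cpp(as_seq_string(seq), pos - 1, filter$ptr)
}

#' Best supported base substitution at a position
#'
#' Permutes the base at `pos` to each of the three alternates (in A<C<G<T
#' order) and counts the filter-present windows containing the change. The
#' alternate with the most support is returned if it reaches the acceptance
#' threshold `ceiling(k / y)`; ties go to the alphabetically first base.
#'
#' @inheritParams assess_position
#' @param y present-k-mer leniency divisor.
#' @return list with `found`, and when found `alt` and `n_support`.
#' @export
try_substitutions <- function(seq, pos, filter, y = 9) {
  stopifnot(inherits(filter, "kmer_filter"))
  try_substitutions_cpp(as_seq_string(seq), pos - 1, filter$ptr, y)
}

#' Best supported micro-indel at a position
#'
#' Tries deletions of 1..`max_indel` bases starting at `pos`, then insertions
#' of up to `max_indel` bases before `pos`, scoring each candidate by the
#' filter-present windows containing the change. The best qualifying
#' candidate wins (most support; ties to the shorter edit, deletions before
#' insertions, then alphabetical bases).
#'
#' @inheritParams try_substitutions
#' @param max_indel largest indel length tried (1-5).
#' @return list with `found`, and when found `kind`, `bases`, `n_support`.
#' @export
try_indels <- function(seq, pos, filter, y = 9, max_indel = 5) {
  stopifnot(inherits(filter, "kmer_filter"))
  try_indels_cpp(as_seq_string(seq), pos - 1, filter$ptr, y, as.integer(max_indel))
}

#' Polish a single contig
#'
#' Scans the contig 5'->3', interrogating the filter with each k-mer. When a
#' k-mer is absent, its 3'-end base is scrutinized: if enough covering k-mers
#' are absent (first leniency factor) the base is permuted to the three
#' alternates and, failing those, micro-insertions and deletions of up to
#' `max_indel` bases are tried; the best change whose containing k-mers are
#' sufficiently present (second leniency factor) is applied, and the scan
#' resumes on the edited sequence at the base following the change.
#'
#' @param seq a single DNA sequence (character or [Biostrings::DNAString]);
#'   sequences shorter than k pass through unedited.
#' @param filter a `kmer_bloom` or `kmer_exact_set` built with the same k.
#' @param config a [polish_config()].
#' @return list with `seq` (edited sequence, character) and `edits`
#'   (data.frame with columns `position` (1-based, on the ORIGINAL input),
#'   `kind`, `ref`, `alt`, `n_missing`, `n_support`).
#' @export
polish_contig <- function(seq, filter, config = polish_config()) {
  stopifnot(inherits(filter, "kmer_filter"), inherits(config, "polish_config"))
  s <- as_seq_string(seq)
  if (nchar(s) < filter$k) {
    message("contig shorter than k (", nchar(s), " < ", filter$k,
            "); passed through unedited")
    return(list(seq = s, edits = empty_edits()))
  }
  res <- polish_contig_cpp(s, filter$ptr, config$x, config$y, config$max_indel,
                           config$mode == "subs+indels")
  res$edits$position <- as.numeric(res$edits$position)
  res
}

empty_edits <- function() {
  data.frame(position = numeric(0), kind = character(0), ref = character(0),
             alt = character(0), n_missing = integer(0),
             n_support = integer(0), stringsAsFactors = FALSE)
}

#' Polish every contig of an assembly
#'
#' Applies [polish_contig()] to each contig in turn, preserving order.
#'
#' @param contigs named character vector or [Biostrings::DNAStringSet] (the
#'   draft assembly).
#' @param filter a `kmer_bloom` or `kmer_exact_set`.
#' @param config a [polish_config()].
#' @param k if given, checked against the filter's k (a mismatch is an error;
#'   the editor and filter must be built with equal k).
#' @return list with `seqs` (edited contigs, named character vector in input
#'   order) and `edits` (one data.frame with a leading `contig` column).
#' @export
polish_assembly <- function(contigs, filter, config = polish_config(), k = NULL) {
  stopifnot(inherits(filter, "kmer_filter"))
  if (!is.null(k) && as.integer(k) != filter$k)
    stop("k mismatch: filter has k = ", filter$k, " but k = ", k,
         " was requested")
  seqs <- as_seq_strings(contigs)
  ids <- names(seqs)
  if (is.null(ids))
    ids <- if (length(seqs)) paste0("contig_", seq_along(seqs)) else character(0)
  out_seqs <- character(length(seqs))
  names(out_seqs) <- ids
  all_edits <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    res <- polish_contig(seqs[[i]], filter, config)
    out_seqs[[i]] <- res$seq
    ed <- res$edits
    if (nrow(ed)) ed <- cbind(contig = ids[[i]], ed, stringsAsFactors = FALSE)
    else ed <- cbind(contig = character(0), ed)
    all_edits[[i]] <- ed
  }
  edits <- do.call(rbind, all_edits)
  if (is.null(edits)) edits <- cbind(contig = character(0), empty_edits())
  rownames(edits) <- NULL
  list(seqs = out_seqs, edits = edits)
}
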