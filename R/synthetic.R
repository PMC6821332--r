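#' Random genome sequence
#'
#' I.i.d. bases at a chosen GC fraction. Deterministic under `seed`.
#'
#' @param length genome length in bases.
#' @param gc target GC fraction (default 0.5).
#' @param seed optional integer seed (uses the current RNG stream if `NULL`).
#' @return a single character string (possibly empty, with a warning).
#' @export
random_genome <- function(length, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (length == 0) {
    warning("generating an empty genome")
    return("")
  }
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = probs),
        collapse = "")
}

#' Mutate a genome into a synthetic "draft" with a recorded truth set
#'
#' Introduces base substitutions at `sub_rate` and micro-indels at
#' `indel_rate` (counts drawn binomially per base; indel lengths uniform on
#' 1..`max_indel_len`, insertions and deletions equally likely). Sites are
#' placed uniformly but kept at least `min_spacing` bases apart and the same
#' distance away from the sequence ends, so each error is an isolated event a
#' k-mer scan can see in full. Every mutation is recorded with both its truth
#' coordinate and its draft coordinate; [apply_truth()] replays the truth set
#' onto the genome and reproduces the draft exactly.
#'
#' @param genome a single DNA sequence (character).
#' @param sub_rate per-base substitution rate, in \[0, 0.01\].
#' @param indel_rate per-base indel rate, in \[0, 0.01\].
#' @param max_indel_len largest indel length (default 5).
#' @param min_spacing minimum distance between mutation sites (and from the
#'   sequence ends). Default `max_indel_len + 1` (non-overlap only); oracle
#'   experiments use `2k + 1`.
#' @param contig contig name recorded in the truth set.
#' @param seed optional integer seed.
#' @return list with `draft` (character) and `truth` (data.frame with columns
#'   `contig`, `pos` (1-based on the truth genome), `pos_draft` (1-based on
#'   the draft), `kind`, `ref`, `alt`), sorted by position.
#' @export
mutate_genome <- function(genome, sub_rate, indel_rate, max_indel_len = 5,
                          min_spacing = NULL, contig = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sub_rate < 0 || sub_rate > 0.01 || indel_rate < 0 || indel_rate > 0.01)
    stop("mutation rates must be in [0, 0.01]")
  genome <- as_seq_string(genome)
  L <- nchar(genome)
  if (is.null(min_spacing)) min_spacing <- max_indel_len + 1
  n_sub <- rbinom(1, L, sub_rate)
  n_indel <- rbinom(1, L, indel_rate)
  n <- n_sub + n_indel
  if (n == 0) {
    return(list(draft = genome, truth = empty_truth()))
  }
  pos <- draw_spaced_positions(n, L, min_spacing)
  is_sub <- rep(FALSE, n)
  is_sub[sample.int(n, n_sub)] <- TRUE

  bases <- c("A", "C", "G", "T")
  kind <- character(n)
  ref <- character(n)
  alt <- character(n)
  for (i in seq_len(n)) {
    p <- pos[i]
    if (is_sub[i]) {
      kind[i] <- "substitution"
      ref[i] <- substr(genome, p, p)
      alt[i] <- sample(setdiff(bases, ref[i]), 1)
    } else {
      len <- sample.int(max_indel_len, 1)
      if (runif(1) < 0.5) {
        kind[i] <- "insertion"  # draft gains bases before truth position p
        ref[i] <- ""
        alt[i] <- paste(sample(bases, len, replace = TRUE), collapse = "")
      } else {
        kind[i] <- "deletion"   # draft loses truth bases p..p+len-1
        ref[i] <- substr(genome, p, p + len - 1)
        alt[i] <- ""
      }
    }
  }
  truth <- data.frame(contig = contig, pos = pos, pos_draft = NA_real_,
                      kind = kind, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  truth$pos_draft <- truth$pos + c(0, cumsum(nchar(truth$alt) - nchar(truth$ref)))[seq_len(n)]
  draft <- apply_truth(genome, truth)
  list(draft = draft, truth = truth)
}

empty_truth <- function() {
  data.frame(contig = character(0), pos = numeric(0), pos_draft = numeric(0),
             kind = character(0), ref = character(0), alt = character(0),
             stringsAsFactors = FALSE)
}

# uniform positions in [gap+1, L-gap] with pairwise distance >= gap
draw_spaced_positions <- function(n, L, gap) {
  lo <- gap + 1
  hi <- L - gap
  if (hi < lo || n * gap > (hi - lo + 1))
    stop("mutation rates too high to honor the requested spacing")
  acc <- numeric(0)
  for (attempt in 1:1000) {
    need <- n - length(acc)
    if (need == 0) break
    cand <- lo + sample.int(hi - lo + 1, min(4 * need + 16, hi - lo + 1)) - 1
    for (p in cand) {
      if (length(acc) == n) break
      if (!length(acc) || min(abs(acc - p)) >= gap) acc <- c(acc, p)
    }
  }
  if (length(acc) < n)
    stop("mutation rates too high to honor the requested spacing")
  sort(acc)
}

#' Replay a truth set onto a genome
#'
#' Applies the recorded mutations (in position order) to the truth genome and
#' returns the mutated sequence; by construction this reproduces the draft
#' emitted by [mutate_genome()] byte for byte.
#'
#' @param genome truth genome (character).
#' @param truth truth data.frame from [mutate_genome()].
#' @return mutated sequence (character).
#' @export
apply_truth <- function(genome, truth) {
  genome <- as_seq_string(genome)
  if (nrow(truth) == 0) return(genome)
  truth <- truth[order(truth$pos), , drop = FALSE]
  pieces <- character(0)
  cursor <- 1
  for (i in seq_len(nrow(truth))) {
    p <- truth$pos[i]
    pieces <- c(pieces, substr(genome, cursor, p - 1))
    if (truth$kind[i] == "substitution") {
      pieces <- c(pieces, truth$alt[i])
      cursor <- p + 1
    } else if (truth$kind[i] == "insertion") {
      pieces <- c(pieces, truth$alt[i])
      cursor <- p
    } else if (truth$kind[i] == "deletion") {
      cursor <- p + nchar(truth$ref[i])
    } else stop("unknown mutation kind '", truth$kind[i], "'")
  }
  pieces <- c(pieces, substr(genome, cursor, nchar(genome)))
  paste(pieces, collapse = "")
}

#' Simulate uniform-coverage error-bearing short reads
#'
#' Read start positions are uniform, strands are drawn 50/50 (reverse-strand
#' reads are reverse complemented), and substitution errors are injected at
#' `error_rate` per base (Illumina-like: no read indels). Total bases equal
#' `coverage * nchar(genome)` up to one read's rounding.
#'
#' @param genome a single DNA sequence (character).
#' @param coverage target mean depth.
#' @param read_len read length (default 150).
#' @param error_rate per-base substitution error rate (default 0).
#' @param seed optional integer seed.
#' @return named character vector of reads.
#' @export
simulate_reads <- function(genome, coverage, read_len = 150, error_rate = 0,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- as_seq_string(genome)
  L <- nchar(genome)
  if (read_len > L) stop("read length exceeds genome length")
  n_reads <- round(coverage * L / read_len)
  if (n_reads == 0) return(character(0))
  starts <- sample.int(L - read_len + 1, n_reads, replace = TRUE)
  reads <- substring(genome, starts, starts + read_len - 1)
  minus <- runif(n_reads) < 0.5
  if (any(minus)) {
    reads[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[minus])))
  }
  if (error_rate > 0) reads <- inject_substitutions_cpp(reads, error_rate)
  names(reads) <- sprintf("read_%d/%s", seq_len(n_reads),
                          ifelse(minus, "-", "+"))
  reads
}

#' Write / read a truth set as TSV
#'
#' @param truth truth data.frame from [mutate_genome()].
#' @param path TSV path.
#' @return `path` (writer) or the truth data.frame (reader).
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  x <- read.delim(path, sep = "\t", header = TRUE,
                  colClasses = c(contig = "character", pos = "numeric",
                                 pos_draft = "numeric", kind = "character",
                                 ref = "character", alt = "character"))
  x$ref[is.na(x$ref)] <- ""
  x$alt[is.na(x$alt)] <- ""
  x
}
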