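# Independent oracles used to cross-check the compiled implementation.
# Deliberately naive base-R / Biostrings code paths.

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

oracle_canonical <- function(x) {
  rc <- oracle_revcomp(x)
  ifelse(x <= rc, x, rc)
}

# all k-length windows of a sequence, in order (no validity filtering)
oracle_windows <- function(seq, k) {
  n <- nchar(seq) - k + 1
  if (n < 1) return(character(0))
  substring(seq, seq_len(n), seq_len(n) + k - 1)
}

# exact canonical k-mer multiset of a set of reads, as a named count table
oracle_count <- function(reads, k) {
  words <- unlist(lapply(reads, oracle_windows, k = k))
  words <- words[!grepl("[^ACGT]", words)]
  table(oracle_canonical(words))
}

# independent patcher: apply a change log to the original draft
oracle_apply_edits <- function(draft, edits) {
  if (nrow(edits) == 0) return(draft)
  edits <- edits[order(edits$position), , drop = FALSE]
  out <- character(0)
  cursor <- 1
  for (i in seq_len(nrow(edits))) {
    p <- edits$position[i]
    out <- c(out, substr(draft, cursor, p - 1))
    kind <- edits$kind[i]
    if (kind == "substitution") {
      out <- c(out, edits$alt[i])
      cursor <- p + 1
    } else if (kind == "deletion") {
      cursor <- p + nchar(edits$ref[i])
    } else if (kind == "insertion") {
      out <- c(out, edits$alt[i])
      cursor <- p
    } else stop("bad kind")
  }
  paste(c(out, substr(draft, cursor, nchar(draft))), collapse = "")
}

# error-free reads tiling every start position (`copies` passes), so that
# every genome k-mer is observed at least `copies` times
tiled_reads <- function(genome, read_len, copies = 2) {
  starts <- seq_len(nchar(genome) - read_len + 1)
  rep(substring(genome, starts, starts + read_len - 1), copies)
}

# random k-mer strings through R-level sampling (not the compiled generator)
oracle_random_kmers <- function(n, k) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
    character(1))
}
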