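#' Read sequences from FASTA or FASTQ (gzip transparent)
#'
#' Detects the format from the first record marker (`>` FASTA, `@` FASTQ) and
#' parses with Biostrings. FASTQ qualities are discarded: the pipeline uses
#' presence/absence of k-mers only. Multi-line FASTA and CRLF line endings
#' are handled by the parser; malformed records raise a parse error.
#'
#' @param path path to a FASTA/FASTQ file, optionally gzipped.
#' @return a [Biostrings::DNAStringSet]; names are the full header lines.
#' @export
read_fastx <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- ""
  while (TRUE) {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    if (nzchar(trimws(line))) { first <- substr(trimws(line), 1L, 1L); break }
  }
  if (first == ">") {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
  } else if (first == "@") {
    validate_fastq(path)  # Biostrings' FASTQ parser does not check structure
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    stop("cannot detect FASTA/FASTQ format of ", path,
         " (first record starts with '", first, "')")
  }
  if (any(Biostrings::width(x) == 0L))
    warning("input contains empty sequence records")
  x
}

# structural check of 4-line FASTQ records; errors carry the offending line
# number (the established parsers accept records whose quality string length
# disagrees with the sequence, which this pipeline treats as malformed input)
validate_fastq <- function(path, block_lines = 40000L) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  ln <- 0L
  repeat {
    block <- readLines(con, n = block_lines)
    nb <- length(block)
    if (nb == 0L) break
    if (nb %% 4L != 0L)
      stop("truncated FASTQ record near line ", ln + nb, " of ", path)
    block <- sub("\r$", "", block)
    heads <- block[seq(1L, nb, 4L)]
    seqs <- block[seq(2L, nb, 4L)]
    seps <- block[seq(3L, nb, 4L)]
    quals <- block[seq(4L, nb, 4L)]
    bad <- which(!startsWith(heads, "@"))
    if (length(bad))
      stop("FASTQ parse error at line ", ln + (bad[1] - 1L) * 4L + 1L,
           ": record header must start with '@'")
    bad <- which(!startsWith(seps, "+"))
    if (length(bad))
      stop("FASTQ parse error at line ", ln + (bad[1] - 1L) * 4L + 3L,
           ": separator line must start with '+'")
    bad <- which(nchar(seqs) != nchar(quals))
    if (length(bad))
      stop("FASTQ parse error at line ", ln + (bad[1] - 1L) * 4L + 4L,
           ": quality string length differs from sequence length")
    ln <- ln + nb
  }
  invisible(TRUE)
}

#' Record ids (first whitespace-delimited header token)
#'
#' @param x a named vector or `DNAStringSet` whose names are header lines.
#' @return character vector of ids.
#' @export
seq_ids <- function(x) {
  nm <- names(x)
  if (is.null(nm)) stop("sequences have no names/headers")
  sub("\\s.*$", "", nm)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet].
#' @param path output path (a `.gz` suffix writes gzip).
#' @param wrap line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, wrap = 60L) {
  seqs <- coerce_stringset(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, format = "fasta",
                              width = as.integer(wrap),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write reads as FASTQ with constant placeholder qualities
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet].
#' @param path output path (a `.gz` suffix writes gzip).
#' @param quality single quality character applied to every base (default
#'   `"I"`, Phred 40); the pipeline never reads qualities back.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, quality = "I") {
  seqs <- coerce_stringset(seqs)
  quals <- Biostrings::BStringSet(vapply(Biostrings::width(seqs), function(w)
    paste(rep(quality, w), collapse = ""), character(1)))
  Biostrings::writeXStringSet(seqs, filepath = path, format = "fastq",
                              qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

coerce_stringset <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) return(seqs)
  nm <- names(seqs)
  seqs <- as.character(seqs)  # as.character() drops names; restore them
  if (is.null(nm)) nm <- if (length(seqs)) paste0("seq_", seq_along(seqs)) else character(0)
  names(seqs) <- nm
  Biostrings::DNAStringSet(seqs)
}

# ---- change log (TSV) ------------------------------------------------------

CHANGES_COLUMNS <- c("contig", "position", "kind", "ref", "alt",
                     "n_missing", "n_support")

#' Write the change log as TSV
#'
#' One row per edit, native (anchor-free) coordinates: `position` is the
#' 1-based position on the original draft of the substituted base, the first
#' deleted base, or the base before which the insertion goes. `ref`/`alt` are
#' empty strings for insertions/deletions respectively. A header line is
#' always included.
#'
#' @param edits data.frame as returned by [polish_assembly()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_changes_tsv <- function(edits, path) {
  stopifnot(all(CHANGES_COLUMNS %in% names(edits)))
  write.table(edits[, CHANGES_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a change log written by [write_changes_tsv()]
#'
#' @param path TSV path.
#' @return data.frame with the change-log columns (empty `ref`/`alt` restored
#'   to `""`).
#' @export
read_changes_tsv <- function(path) {
  x <- read.delim(path, sep = "\t", header = TRUE,
                  colClasses = c(contig = "character", position = "numeric",
                                 kind = "character", ref = "character",
                                 alt = "character", n_missing = "integer",
                                 n_support = "integer"))
  x$ref[is.na(x$ref)] <- ""
  x$alt[is.na(x$alt)] <- ""
  x
}

# ---- VCF -------------------------------------------------------------------

#' Write edits as VCF 4.2
#'
#' Substitutions become SNV lines; indels are left-anchored on the previous
#' base per VCF convention (or on the following base for an event at position
#' 1). Every emitted REF is checked against the draft sequence; a mismatch is
#' an error, which guards against coordinate bookkeeping bugs upstream.
#'
#' @param edits change-log data.frame (draft coordinates).
#' @param draft the draft assembly the edits refer to (named character vector
#'   or [Biostrings::DNAStringSet]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(edits, draft, path) {
  stopifnot(all(c("contig", "position", "kind", "ref", "alt") %in% names(edits)))
  draft <- as_seq_strings(coerce_stringset(draft))
  names(draft) <- sub("\\s.*$", "", names(draft))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=kmerpolish",
    "##INFO=<ID=KMISS,Number=1,Type=Integer,Description=\"Absent covering k-mers that triggered the edit\">",
    "##INFO=<ID=KSUP,Number=1,Type=Integer,Description=\"Present k-mers supporting the accepted change\">",
    sprintf("##contig=<ID=%s,length=%d>", names(draft), nchar(draft)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- character(0)
  if (nrow(edits)) {
    edits <- edits[order(match(edits$contig, names(draft)), edits$position), ,
                   drop = FALSE]
    lines <- vapply(seq_len(nrow(edits)), function(i) {
      e <- edits[i, ]
      s <- draft[[e$contig]]
      if (is.null(s)) stop("edit refers to unknown contig '", e$contig, "'")
      p <- e$position
      if (e$kind == "substitution") {
        pos <- p; ref <- e$ref; alt <- e$alt
      } else if (e$kind == "deletion") {
        d <- nchar(e$ref)
        if (p > 1) {
          pos <- p - 1
          ref <- substr(s, p - 1, p + d - 1)
          alt <- substr(s, p - 1, p - 1)
        } else {
          pos <- 1
          ref <- substr(s, 1, d + 1)
          alt <- substr(s, d + 1, d + 1)
        }
      } else if (e$kind == "insertion") {
        if (p > 1) {
          pos <- p - 1
          ref <- substr(s, p - 1, p - 1)
          alt <- paste0(ref, e$alt)
        } else {
          pos <- 1
          ref <- substr(s, 1, 1)
          alt <- paste0(e$alt, ref)
        }
      } else stop("unknown edit kind '", e$kind, "'")
      if (!identical(substr(s, pos, pos + nchar(ref) - 1), ref))
        stop("REF/draft mismatch at ", e$contig, ":", pos,
             " (edit ref does not match the draft sequence)")
      info <- if (all(c("n_missing", "n_support") %in% names(e)))
        sprintf("KMISS=%d;KSUP=%d", e$n_missing, e$n_support) else "."
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", e$contig, as.integer(pos),
              ref, alt, info)
    }, character(1))
    # the native-coordinate check: for substitutions/deletions the recorded
    # ref must equal the draft slice at the recorded position
    for (i in seq_len(nrow(edits))) {
      e <- edits[i, ]
      if (nchar(e$ref) > 0) {
        s <- draft[[e$contig]]
        if (!identical(substr(s, e$position, e$position + nchar(e$ref) - 1), e$ref))
          stop("edit ref '", e$ref, "' does not match draft at ", e$contig,
               ":", e$position)
      }
    }
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
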