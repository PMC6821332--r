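#' Score an edit set against a ground-truth mutation set
#'
#' Each truth mutation implies a corrective edit on the draft (a truth
#' substitution is reverted by a substitution; bases the mutator inserted
#' must be deleted; bases it deleted must be re-inserted). An emitted edit is
#' a true positive iff an unmatched truth mutation of the corresponding kind
#' lies within the positional tolerance AND applying the edit to the local
#' draft sequence restores the local truth sequence. The sequence-restoration
#' criterion is stricter than coordinate matching but immune to the left/right
#' placement ambiguity of indels in repetitive context (an equivalent indel
#' shifted within a homopolymer still scores TP). Matching is greedy
#' nearest-first; unmatched edits are false positives and unmatched truths
#' false negatives.
#'
#' @param edits change-log data.frame (draft coordinates), e.g. from
#'   [polish_assembly()]; must contain `contig`, `position`, `kind`, `ref`,
#'   `alt`. Duplicate (contig, position) rows are an error.
#' @param truth truth data.frame from [mutate_genome()].
#' @param draft the draft assembly (named character or `DNAStringSet`); names
#'   must cover the contigs appearing in `edits`/`truth`.
#' @param genome the truth genome (same form).
#' @param window_sub positional tolerance for substitutions (default 0).
#' @param window_indel positional tolerance for indels (default 5).
#' @return object of class `eval_report`: list with `tp`, `fp`, `fn`,
#'   `recall` (= tp / (tp + fn)), `fdr` (= fp / (tp + fp), 0 when no edits).
#' @export
compare_edits <- function(edits, truth, draft, genome,
                          window_sub = 0, window_indel = 5) {
  draft <- named_seqs(draft)
  genome <- named_seqs(genome)
  if (nrow(edits) && anyDuplicated(edits[, c("contig", "position")]))
    stop("duplicate edit positions: the editor must not emit two edits at one position")

  n_edits <- nrow(edits)
  n_truth <- nrow(truth)
  edit_matched <- rep(FALSE, n_edits)
  truth_matched <- rep(FALSE, n_truth)

  if (n_edits && n_truth) {
    # corrective kind implied by each truth mutation
    corrective <- c(substitution = "substitution",
                    insertion = "deletion",
                    deletion = "insertion")[truth$kind]
    cand <- NULL
    for (e in seq_len(n_edits)) {
      w <- if (edits$kind[e] == "substitution") window_sub else window_indel
      t_idx <- which(truth$contig == edits$contig[e] &
                       corrective == edits$kind[e] &
                       abs(truth$pos_draft - edits$position[e]) <= w)
      if (length(t_idx))
        cand <- rbind(cand, data.frame(
          e = e, t = t_idx,
          dist = abs(truth$pos_draft[t_idx] - edits$position[e])))
    }
    if (!is.null(cand)) {
      cand <- cand[order(cand$dist, cand$e, cand$t), , drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        e <- cand$e[i]; t <- cand$t[i]
        if (edit_matched[e] || truth_matched[t]) next
        if (edit_restores_truth(edits[e, ], truth[t, ], draft, genome,
                                pad = 12 + window_indel)) {
          edit_matched[e] <- TRUE
          truth_matched[t] <- TRUE
        }
      }
    }
  }

  tp <- sum(edit_matched)
  fp <- n_edits - tp
  fn <- n_truth - tp
  structure(list(
    tp = tp, fp = fp, fn = fn,
    recall = if (tp + fn == 0) 1 else tp / (tp + fn),
    fdr = if (tp + fp == 0) 0 else fp / (tp + fp)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("edit evaluation: TP=%d FP=%d FN=%d | recall=%.4f FDR=%.4f\n",
              x$tp, x$fp, x$fn, x$recall, x$fdr))
  invisible(x)
}

# Does applying `edit` to the draft locally reproduce the truth sequence
# around this (isolated) truth mutation site?
edit_restores_truth <- function(edit, tr, draft, genome, pad = 17) {
  di <- match(edit$contig, names(draft))
  gi <- match(tr$contig, names(genome))
  if (is.na(di) || is.na(gi)) stop("unknown contig in edits/truth")
  ds <- draft[[di]]
  gs <- genome[[gi]]

  shiftL <- tr$pos - tr$pos_draft              # draft -> truth left of the site
  shiftR <- shiftL + nchar(tr$ref) - nchar(tr$alt)  # right of the site

  site_lo <- min(edit$position, tr$pos_draft)
  site_hi <- max(edit$position + max(nchar(edit$ref), 1) - 1,
                 tr$pos_draft + max(nchar(tr$alt), 1) - 1)
  dlo <- site_lo - pad
  dhi <- site_hi + pad
  # clamp consistently so draft and truth windows stay aligned
  dlo <- max(dlo, 1, 1 - shiftL)
  dhi <- min(dhi, nchar(ds), nchar(gs) - shiftR)
  if (dlo > dhi) return(FALSE)

  region <- substr(ds, dlo, dhi)
  q <- edit$position - dlo + 1                 # edit position inside region
  if (q < 1 || q > nchar(region) + 1) return(FALSE)
  patched <- switch(edit$kind,
    substitution = paste0(substr(region, 1, q - 1), edit$alt,
                          substr(region, q + 1, nchar(region))),
    deletion = paste0(substr(region, 1, q - 1),
                      substr(region, q + nchar(edit$ref), nchar(region))),
    insertion = paste0(substr(region, 1, q - 1), edit$alt,
                       substr(region, q, nchar(region))),
    stop("unknown edit kind '", edit$kind, "'"))
  truth_region <- substr(gs, dlo + shiftL, dhi + shiftR)
  identical(patched, truth_region)
}

named_seqs <- function(x) {
  s <- as_seq_strings(coerce_stringset(x))
  names(s) <- sub("\\s.*$", "", names(s))
  s
}
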