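#' Run one simulate-build-polish-evaluate experiment
#'
#' Generates a random genome, mutates it into a draft at the given
#' substitution/indel rates (sites isolated by more than 2k bases), simulates
#' error-bearing short reads, builds the coverage-thresholded Bloom filter,
#' polishes the draft, and scores the edits against the truth set. This is
#' the desk-scale analogue of a controlled polishing benchmark.
#'
#' @param genome_length truth genome length (default 1e6).
#' @param sub_rate,indel_rate per-base mutation rates for the draft
#'   (defaults 0.001 each).
#' @param max_indel_len largest simulated indel (default 5).
#' @param coverage read depth (default 20).
#' @param read_len read length (default 150).
#' @param error_rate per-base read substitution error rate (default 0.005).
#' @param k k-mer length (default 25).
#' @param p_target Bloom filter design FPR (default 0.0005).
#' @param c_min coverage threshold or `"auto"` (default).
#' @param config a [polish_config()].
#' @param seed integer seed driving the whole experiment.
#' @param gc genome GC fraction (default 0.5).
#' @param verbose print progress.
#' @return list with `report` (an `eval_report`), `edits`, `truth`, `c_min`,
#'   and the polished assembly in `polished`.
#' @export
polish_experiment <- function(genome_length = 1e6, sub_rate = 0.001,
                              indel_rate = 0.001, max_indel_len = 5,
                              coverage = 20, read_len = 150,
                              error_rate = 0.005, k = 25, p_target = 0.0005,
                              c_min = "auto", config = polish_config(),
                              seed = 1, gc = 0.5, verbose = FALSE) {
  set.seed(seed)
  genome <- random_genome(genome_length, gc = gc)
  mut <- mutate_genome(genome, sub_rate, indel_rate,
                       max_indel_len = max_indel_len,
                       min_spacing = 2 * k + 1, contig = "chr1")
  reads <- simulate_reads(genome, coverage, read_len = read_len,
                          error_rate = error_rate)
  bf <- build_filter(reads, k, c_min = c_min, p_target = p_target,
                     verbose = verbose)
  res <- polish_assembly(c(chr1 = mut$draft), bf, config)
  report <- compare_edits(res$edits, mut$truth, c(chr1 = mut$draft),
                          c(chr1 = genome))
  if (verbose) print(report)
  list(report = report, edits = res$edits, truth = mut$truth,
       c_min = attr(bf, "c_min"), polished = res$seqs)
}

#' Sweep a grid of polishing conditions
#'
#' Runs [polish_experiment()] for every combination of `coverage` and `k`
#' values, for each seed, and returns a tidy table of evaluation metrics.
#'
#' @param coverages numeric vector of read depths.
#' @param ks integer vector of k-mer lengths.
#' @param seeds integer vector of seeds (one run per grid cell per seed).
#' @param ... further arguments passed to [polish_experiment()]
#'   (`genome_length`, rates, `read_len`, `error_rate`, ...).
#' @return data.frame with one row per run: `coverage`, `k`, `seed`, `tp`,
#'   `fp`, `fn`, `recall`, `fdr`, `n_edits`.
#' @export
sweep_polish <- function(coverages, ks, seeds = 1L, ...) {
  grid <- expand.grid(coverage = coverages, k = ks, seed = seeds)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    res <- polish_experiment(coverage = grid$coverage[i], k = grid$k[i],
                             seed = grid$seed[i], ...)
    r <- res$report
    data.frame(coverage = grid$coverage[i], k = grid$k[i],
               seed = grid$seed[i], tp = r$tp, fp = r$fp, fn = r$fn,
               recall = r$recall, fdr = r$fdr, n_edits = nrow(res$edits))
  })
  do.call(rbind, rows)
}
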