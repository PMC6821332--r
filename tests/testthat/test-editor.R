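# Exact-set oracle: with the truth genome's k-mer set standing in for the
# Bloom filter the editor's behavior is fully deterministic and checkable.

make_oracle <- function(genome, k = 25) genome_kmer_set(genome, k)

test_that("assess_position counts absent windows over the available ones", {
  set.seed(51)
  g <- random_genome(3000)
  k <- 25
  es <- make_oracle(g, k)
  # clean position: nothing missing
  a <- assess_position(g, 1500, es)
  expect_identical(a, list(n_missing = 0L, n_valid = 25L))
  # single substitution: every covering window goes absent
  d <- g
  substr(d, 1500, 1500) <- setdiff(c("A", "C", "G", "T"),
                                   substr(g, 1500, 1500))[1]
  a2 <- assess_position(d, 1500, es)
  expect_identical(a2$n_valid, 25L)
  expect_identical(a2$n_missing, 25L)
  # near the contig start the denominator shrinks to the available windows
  a3 <- assess_position(d, 10, es)
  expect_identical(a3$n_valid, 10L)  # starts 1..10 only
})

test_that("try_substitutions restores the truth base with full support", {
  set.seed(52)
  g <- random_genome(3000)
  es <- make_oracle(g)
  truth_base <- substr(g, 1200, 1200)
  d <- g
  substr(d, 1200, 1200) <- setdiff(c("A", "C", "G", "T"), truth_base)[1]
  r <- try_substitutions(d, 1200, es)
  expect_true(r$found)
  expect_identical(r$alt, truth_base)
  expect_identical(r$n_support, 25L)
  # a clean position offers no qualifying alternate
  expect_false(try_substitutions(g, 1200, es)$found)
})

test_that("tied substitution alternates resolve to the alphabetically first", {
  set.seed(53)
  flank_l <- random_genome(60)
  flank_r <- random_genome(60)
  truth_c <- paste0(flank_l, "C", flank_r)
  truth_g <- paste0(flank_l, "G", flank_r)
  draft <- paste0(flank_l, "A", flank_r)
  es <- exact_kmer_set(25)
  kmerpolish:::exact_set_add_seq(es$ptr, c(truth_c, truth_g))
  r <- try_substitutions(draft, 61, es)
  expect_true(r$found)
  expect_identical(r$alt, "C")  # C and G have equal support
})

test_that("try_indels recovers micro-indels and respects the length bound", {
  set.seed(54)
  g <- random_genome(4000)
  es <- make_oracle(g)
  # draft missing 2 bases: insertion of the truth bases
  d <- paste0(substr(g, 1, 2000), substr(g, 2003, nchar(g)))
  r <- try_indels(d, 2001, es)
  expect_true(r$found)
  expect_identical(r$kind, "insertion")
  res <- polish_contig(d, es)
  expect_identical(res$seq, g)
  expect_identical(unique(res$edits$kind), "insertion")

  # draft with 3 extra bases: deletion of length 3
  d2 <- paste0(substr(g, 1, 1000), "TCA", substr(g, 1001, nchar(g)))
  r2 <- try_indels(d2, 1001, es)
  expect_true(r2$found)
  expect_identical(r2$kind, "deletion")
  expect_identical(nchar(r2$bases), 3L)
  res2 <- polish_contig(d2, es)
  expect_identical(res2$seq, g)

  # a 6-base deletion exceeds max_indel = 5: the position is left unedited
  d3 <- paste0(substr(g, 1, 3000), substr(g, 3007, nchar(g)))
  res3 <- polish_contig(d3, es)
  expect_identical(nrow(res3$edits), 0L)
  expect_identical(res3$seq, d3)
})

test_that("a draft identical to the truth is returned untouched", {
  set.seed(55)
  g <- random_genome(5000)
  es <- make_oracle(g)
  res <- polish_contig(g, es)
  expect_identical(res$seq, g)
  expect_identical(nrow(res$edits), 0L)
})

test_that("isolated errors on a 30 kb genome are reverted exactly", {
  set.seed(56)
  k <- 25
  g <- random_genome(30000)
  mut <- mutate_genome(g, 0.002, 0.002, min_spacing = 2 * k + 1)
  es <- make_oracle(g, k)
  res <- polish_contig(mut$draft, es)
  expect_identical(res$seq, g)

  # every edit record refers to its original draft coordinates
  for (i in seq_len(nrow(res$edits))) {
    e <- res$edits[i, ]
    if (nchar(e$ref) > 0)
      expect_identical(substr(mut$draft, e$position,
                              e$position + nchar(e$ref) - 1), e$ref)
  }
  # n_missing/n_support satisfy the leniency thresholds (x = 5, y = 9)
  expect_true(all(res$edits$n_missing >= ceiling(k / 5)))
  expect_true(all(res$edits$n_support >= ceiling(k / 9)))

  # self-consistency: an independent patcher reproduces the output
  expect_identical(oracle_apply_edits(mut$draft, res$edits), res$seq)

  # scored against the truth set: full recall, no false discoveries
  edits <- cbind(contig = "chr1", res$edits, stringsAsFactors = FALSE)
  rep <- compare_edits(edits, mut$truth, c(chr1 = mut$draft), c(chr1 = g))
  expect_identical(rep$recall, 1)
  expect_identical(rep$fdr, 0)
})

test_that("re-polishing a polished sequence is quiescent", {
  set.seed(57)
  g <- random_genome(15000)
  mut <- mutate_genome(g, 0.002, 0.002, min_spacing = 51)
  es <- make_oracle(g)
  once <- polish_contig(mut$draft, es)
  twice <- polish_contig(once$seq, es)
  expect_identical(nrow(twice$edits), 0L)
  expect_identical(twice$seq, once$seq)
})

test_that("stricter leniency factors never increase the edit count", {
  set.seed(58)
  g <- random_genome(15000)
  mut <- mutate_genome(g, 0.002, 0.002, min_spacing = 51)
  es <- make_oracle(g)
  n_edits <- function(x, y) nrow(polish_contig(mut$draft, es,
                                               polish_config(x = x, y = y))$edits)
  base <- n_edits(5, 9)
  for (x in c(6, 9, 25)) expect_lte(n_edits(x, 9), base)
  for (y in c(5, 3, 1)) expect_lte(n_edits(5, y), base)
})

test_that("polish_assembly preserves contig order and per-contig records", {
  set.seed(59)
  g1 <- random_genome(4000)
  g2 <- random_genome(4000)
  es <- exact_kmer_set(25)
  kmerpolish:::exact_set_add_seq(es$ptr, c(g1, g2))
  d2 <- g2
  substr(d2, 2000, 2000) <- setdiff(c("A", "C", "G", "T"),
                                    substr(g2, 2000, 2000))[1]
  res <- polish_assembly(c(clean = g1, mutated = d2), es)
  expect_identical(names(res$seqs), c("clean", "mutated"))
  expect_identical(res$seqs[["clean"]], g1)
  expect_identical(res$seqs[["mutated"]], g2)
  expect_identical(res$edits$contig, "mutated")

  empty <- polish_assembly(character(0), es)
  expect_identical(length(empty$seqs), 0L)
  expect_identical(nrow(empty$edits), 0L)

  expect_error(polish_assembly(c(a = g1), es, k = 31), "k mismatch")
  expect_message(short <- polish_contig("ACGTACGT", es), "shorter than k")
  expect_identical(short$seq, "ACGTACGT")
})

test_that("substitutions-only mode leaves indels alone", {
  set.seed(60)
  g <- random_genome(4000)
  es <- make_oracle(g)
  d <- paste0(substr(g, 1, 2000), substr(g, 2003, nchar(g)))  # 2 bp missing
  res <- polish_contig(d, es, polish_config(mode = "substitutions-only"))
  expect_identical(nrow(res$edits), 0L)
  expect_identical(res$seq, d)
})
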