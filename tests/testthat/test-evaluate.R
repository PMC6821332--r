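# small deterministic scenario: a genome, a mutated draft, and the exact-set
# polisher providing a perfect corrective edit list to perturb
make_scenario <- function(seed = 95, n = 20000, rate = 0.001) {
  set.seed(seed)
  g <- random_genome(n)
  mut <- mutate_genome(g, rate, rate, min_spacing = 51)
  es <- genome_kmer_set(g, 25)
  res <- polish_contig(mut$draft, es)
  list(genome = c(chr1 = g), draft = c(chr1 = mut$draft), truth = mut$truth,
       edits = cbind(contig = "chr1", res$edits, stringsAsFactors = FALSE))
}

test_that("perfect correction scores recall 1 and FDR 0", {
  sc <- make_scenario()
  rep <- compare_edits(sc$edits, sc$truth, sc$draft, sc$genome)
  expect_identical(rep$tp, nrow(sc$truth))
  expect_identical(rep$fp, 0L)
  expect_identical(rep$fn, 0L)
  expect_identical(rep$recall, 1)
  expect_identical(rep$fdr, 0)
})

test_that("no edits means recall 0 and FDR 0", {
  sc <- make_scenario(96)
  rep <- compare_edits(sc$edits[0, ], sc$truth, sc$draft, sc$genome)
  expect_identical(rep$tp, 0L)
  expect_identical(rep$recall, 0)
  expect_identical(rep$fdr, 0)
})

test_that("spurious edits are counted as false discoveries", {
  sc <- make_scenario(97)
  ten <- sc$edits[1:10, ]
  spurious <- ten[1, ]
  spurious$position <- spurious$position + 500  # far from any truth site
  spurious$kind <- "substitution"
  spurious$ref <- substr(sc$draft[["chr1"]], spurious$position, spurious$position)
  spurious$alt <- setdiff(c("A", "C", "G", "T"), spurious$ref)[1]
  rep <- compare_edits(rbind(ten, spurious), sc$truth, sc$draft, sc$genome)
  expect_identical(rep$tp, 10L)
  expect_identical(rep$fp, 1L)
  expect_equal(rep$fdr, 1 / 11)
  expect_identical(rep$fn, nrow(sc$truth) - 10L)
})

test_that("an equivalently placed indel inside a homopolymer still scores TP", {
  set.seed(98)
  left <- random_genome(50)
  right <- random_genome(50)
  genome <- paste0(left, "AAAAA", right)       # truth has a 5-A run
  # the mutator deleted one A at the run start (truth pos 51)
  truth <- data.frame(contig = "chr1", pos = 51, pos_draft = 51,
                      kind = "deletion", ref = "A", alt = "",
                      stringsAsFactors = FALSE)
  draft <- apply_truth(genome, truth)
  # the editor re-inserted an A at the run END instead (shifted by 4)
  edit <- data.frame(contig = "chr1", position = 55, kind = "insertion",
                     ref = "", alt = "A", n_missing = 10L, n_support = 10L,
                     stringsAsFactors = FALSE)
  rep <- compare_edits(edit, truth, c(chr1 = draft), c(chr1 = genome))
  expect_identical(rep$tp, 1L)
  expect_identical(rep$fdr, 0)
  # whereas inserting the wrong base there is a FP and the truth stays FN
  bad <- edit
  bad$alt <- "C"
  rep2 <- compare_edits(bad, truth, c(chr1 = draft), c(chr1 = genome))
  expect_identical(rep2$tp, 0L)
  expect_identical(rep2$fp, 1L)
  expect_identical(rep2$fn, 1L)
})

test_that("duplicate edit positions are rejected", {
  sc <- make_scenario(99)
  dup <- rbind(sc$edits, sc$edits[1, ])
  expect_error(compare_edits(dup, sc$truth, sc$draft, sc$genome), "duplicate")
})

test_that("matching never exceeds either side's count", {
  for (seed in 101:103) {
    sc <- make_scenario(seed, n = 8000, rate = 0.002)
    keep <- seq_len(nrow(sc$edits)) %% 2 == 1   # drop every other edit
    rep <- compare_edits(sc$edits[keep, ], sc$truth, sc$draft, sc$genome)
    expect_lte(rep$tp, min(sum(keep), nrow(sc$truth)))
    expect_identical(rep$tp + rep$fn, nrow(sc$truth))
    expect_identical(rep$tp + rep$fp, sum(keep))
  }
})

test_that("sweep_polish returns one scored row per grid cell", {
  tab <- sweep_polish(coverages = c(15, 30), ks = 21, seeds = 1,
                      genome_length = 30000, sub_rate = 0.001,
                      indel_rate = 0.001, error_rate = 0.005)
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("coverage", "k", "seed", "recall", "fdr") %in% names(tab)))
  expect_true(all(tab$recall >= 0 & tab$recall <= 1))
  # higher coverage should not cost much recall (sanity trend)
  expect_gte(tab$recall[tab$coverage == 30], tab$recall[tab$coverage == 15] - 0.02)
})
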