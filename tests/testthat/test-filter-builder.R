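test_that("canonical k-mer counting matches a naive oracle", {
  ct <- count_kmers(rep("ACGTACGT", 3), 4)
  # hand enumeration: per read ACGT x2, CGTA x1, GTAC x1, TACG x1;
  # TACG canonicalizes onto CGTA, so counts are ACGT 6, CGTA 6, GTAC 3
  expect_identical(kmer_multiplicity(ct, c("ACGT", "CGTA", "GTAC", "TACG")),
                   c(6L, 6L, 3L, 6L))
  hist <- kmer_histogram(ct)
  expect_identical(hist$multiplicity, c(3L, 6L))
  expect_identical(hist$n_kmers, c(1, 2))

  # the same answer as the independent table-based oracle on random reads
  set.seed(21)
  reads <- vapply(1:30, function(i) random_genome(80), character(1))
  reads[5] <- paste0(substr(reads[5], 1, 40), "N", substr(reads[5], 41, 80))
  ct2 <- count_kmers(reads, 11)
  orc <- oracle_count(reads, 11)
  expect_equal(kcs <- sum(kmer_histogram(ct2)$n_kmers), length(orc))
  expect_identical(kmer_multiplicity(ct2, names(orc)),
                   as.integer(unname(orc)))
})

test_that("degenerate read inputs are handled", {
  expect_warning(ct <- count_kmers("ACG", 4), "no valid k-mers")
  expect_identical(nrow(kmer_histogram(ct)), 0L)
  ct2 <- count_kmers("AAAA", 4)
  expect_identical(kmer_multiplicity(ct2, "AAAA"), 1L)
  expect_identical(kmer_histogram(ct2),
                   data.frame(multiplicity = 1L, n_kmers = 1))
})

test_that("auto threshold lands in the valley between error and coverage modes", {
  hist <- data.frame(multiplicity = 1:8,
                     n_kmers = c(1e6, 2e5, 5e4, 4e4, 6e4, 9e4, 8e4, 2e4))
  expect_identical(select_threshold(hist), 4L)

  # strictly decreasing: no interior minimum, fall back to 2
  dec <- data.frame(multiplicity = 1:5, n_kmers = c(100, 50, 20, 10, 5))
  expect_warning(t2 <- select_threshold(dec), "falling back")
  expect_identical(t2, 2L)

  # sparse histogram with a clean gap: any valley retains the signal mode
  sp <- data.frame(multiplicity = c(1L, 20L), n_kmers = c(5, 1000))
  t3 <- select_threshold(sp)
  expect_true(t3 >= 2 && t3 <= 20)
})

test_that("build_filter keeps exactly the solid k-mers", {
  set.seed(31)
  genome <- random_genome(10000)
  reads <- tiled_reads(genome, read_len = 100)
  genome_kmers <- unique(oracle_canonical(oracle_windows(genome, 21)))

  bf <- build_filter(reads, 21, c_min = 2, verbose = FALSE)
  # error-free full-tiling coverage at c_min 2 recovers the genome k-mer set
  expect_equal(attr(bf, "n_solid"), length(genome_kmers))
  expect_true(all(kmer_contains(bf, genome_kmers)))

  # c_min = 1 disables error removal: superset of the genome set
  bf1 <- build_filter(reads, 21, c_min = 1, verbose = FALSE)
  expect_gte(attr(bf1, "n_solid"), length(genome_kmers))
  expect_true(all(kmer_contains(bf1, genome_kmers)))

  expect_error(build_filter(reads, 21, c_min = 10000, verbose = FALSE),
               "lower c_min")
})

test_that("raising c_min never adds k-mers to the filter", {
  set.seed(32)
  genome <- random_genome(5000)
  reads <- simulate_reads(genome, coverage = 15, read_len = 100,
                          error_rate = 0.01)
  ct <- count_kmers(reads, 17)
  solid <- vapply(1:8, function(cm) kmerpolish:::kcs_n_solid(ct$ptr, cm),
                  numeric(1))
  expect_true(all(diff(solid) <= 0))
})

test_that("auto thresholding on error-bearing reads keeps the genome k-mers", {
  set.seed(33)
  genome <- random_genome(20000)
  reads <- simulate_reads(genome, coverage = 20, read_len = 100,
                          error_rate = 0.01)
  bf <- build_filter(reads, 21, c_min = "auto", verbose = FALSE)
  expect_gte(attr(bf, "c_min"), 2L)
  genome_kmers <- unique(oracle_canonical(oracle_windows(genome, 21)))
  frac <- mean(kmer_contains(bf, genome_kmers))
  expect_gte(frac, 0.99)
})

test_that("count_kmers accepts read files and DNAStringSet input", {
  set.seed(34)
  genome <- random_genome(2000)
  reads <- simulate_reads(genome, coverage = 5, read_len = 100)
  fq <- withr::local_tempfile(fileext = ".fq.gz")
  write_fastq(reads, fq)
  ct_file <- count_kmers(fq, 15)
  ct_mem <- count_kmers(Biostrings::DNAStringSet(reads), 15)
  expect_identical(kmer_histogram(ct_file), kmer_histogram(ct_mem))
})
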