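test_that("canonical_kmer returns the lexicographically smaller strand", {
  expect_identical(canonical_kmer("ACGT"), "ACGT")   # rc palindrome
  expect_identical(canonical_kmer("TTTT"), "AAAA")
  # brute-force compare with the reverse complement oracle
  expect_identical(canonical_kmer("GATTACA"), "GATTACA")
  expect_identical(oracle_revcomp("GATTACA"), "TGTAATC")

  set.seed(42)
  words <- oracle_random_kmers(200, 13)
  expect_identical(canonical_kmer(words), oracle_canonical(words))
  # involution + strand invariance
  cc <- canonical_kmer(words)
  expect_identical(canonical_kmer(cc), cc)
  expect_identical(canonical_kmer(oracle_revcomp(words)), cc)
  # lowercase input is uppercased first
  expect_identical(canonical_kmer("tttt"), "AAAA")
  expect_error(canonical_kmer("ACNT"), "non-ACGT")
})

test_that("kmer_windows enumerates 5'->3' windows and flags non-ACGT", {
  w <- kmer_windows("ACGTA", 4)
  expect_identical(w$start, 1:2)
  expect_identical(w$kmer, c("ACGT", "CGTA"))  # canonical(CGTA) vs TACG
  expect_true(all(w$valid))

  expect_identical(nrow(kmer_windows("ACG", 4)), 0L)

  # every window overlapping the N is invalid
  w2 <- kmer_windows("ACNGTACG", 4)
  expect_identical(w2$valid, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_true(all(is.na(w2$kmer[!w2$valid])))
  expect_identical(w2$kmer[4], canonical_kmer("GTAC"))
})

test_that("rolling window digests equal direct re-hash of each window", {
  set.seed(7)
  for (k in c(5L, 25L, 45L, 64L)) {
    seq <- random_genome(10000)
    # sprinkle a few ambiguous bases
    substr(seq, 500, 500) <- "N"
    substr(seq, 7777, 7777) <- "N"
    rolled <- kmerpolish:::kmer_hashes_rolling(seq, k)
    wins <- oracle_windows(seq, k)
    valid <- !grepl("N", wins)
    direct <- kmerpolish:::kmer_hashes_direct(wins[valid], k)
    expect_identical(rolled[valid], direct)
    expect_true(all(is.na(rolled[!valid])))
  }
})

test_that("bloom_dimensions follows the standard sizing formulas", {
  d <- bloom_dimensions(1e6, 0.0005)
  expect_equal(d$m, 15820283)  # ceil(-n ln p / (ln 2)^2), approx 1.582e7 bits
  expect_identical(d$h, 11L)
  # tiny n: h floored at 1
  expect_identical(bloom_dimensions(1, 0.5), list(m = 2, h = 1L))
  expect_error(bloom_dimensions(1e3, 0), "between 0 and 1")
  expect_error(bloom_dimensions(1e3, 1), "between 0 and 1")
  expect_error(bloom_dimensions(0, 0.01), ">= 1")
})

test_that("inserted k-mers always query TRUE, on either strand", {
  set.seed(11)
  kms <- unique(oracle_random_kmers(3000, 25))
  bf <- kmer_bloom(25, length(kms))
  kmer_insert(bf, kms)
  expect_true(all(kmer_contains(bf, kms)))            # no false negatives
  expect_true(all(kmer_contains(bf, oracle_revcomp(kms))))  # strand symmetry
  expect_equal(filter_info(bf)$n_inserted, length(kms))
  expect_error(kmer_contains(bf, "ACGT"), "does not match k")
  expect_true(is.na(kmer_contains(bf, paste(rep("N", 25), collapse = ""))))
  expect_error(kmer_bloom(70, 10), "k must be between 4 and 64")
})

test_that("empirical FPR stays within a 3x band of the design rate", {
  set.seed(23)
  p <- 0.002
  res <- bloom_fpr_experiment(n_insert = 2e5, n_probe = 2e5, k = 25,
                              p_target = p)
  expect_gt(res$fpr, p / 3)
  expect_lt(res$fpr, 3 * p)
})

test_that("exact k-mer sets behave as a zero-FPR membership oracle", {
  set.seed(3)
  g <- random_genome(2000)
  es <- genome_kmer_set(g, 21)
  wins <- oracle_windows(g, 21)
  expect_true(all(kmer_contains(es, wins)))
  expect_equal(filter_info(es)$n_inserted,
               length(unique(oracle_canonical(wins))))
  probes <- oracle_random_kmers(500, 21)
  novel <- !(oracle_canonical(probes) %in% oracle_canonical(wins))
  expect_false(any(kmer_contains(es, probes)[novel]))
})

test_that("a saved filter reloads with identical header, bits and queries", {
  set.seed(19)
  kms <- unique(oracle_random_kmers(2000, 31))
  bf <- kmer_bloom(31, length(kms), p_target = 0.001)
  kmer_insert(bf, kms)
  path <- withr::local_tempfile(fileext = ".bloom")
  save_kmer_bloom(bf, path)
  bf2 <- load_kmer_bloom(path)
  expect_identical(filter_info(bf2), filter_info(bf))
  probes <- c(kms, oracle_random_kmers(10000, 31))
  expect_identical(kmer_contains(bf2, probes), kmer_contains(bf, probes))
})

test_that("an empty filter round-trips and rejects all probes", {
  bf <- kmer_bloom(25, 100)
  path <- withr::local_tempfile()
  save_kmer_bloom(bf, path)
  bf2 <- load_kmer_bloom(path)
  expect_equal(filter_info(bf2)$n_inserted, 0)
  set.seed(4)
  expect_false(any(kmer_contains(bf2, oracle_random_kmers(1000, 25))))
})

test_that("filter files with wrong k, magic or truncation are refused", {
  bf <- kmer_bloom(25, 100)
  path <- withr::local_tempfile()
  save_kmer_bloom(bf, path)
  expect_error(load_kmer_bloom(path, k = 31), "k mismatch")
  expect_silent(load_kmer_bloom(path, k = 25))

  bad <- withr::local_tempfile()
  writeBin(charToRaw("NOTAFILTER"), bad)
  expect_error(load_kmer_bloom(bad, k = 25), "magic")

  trunc <- withr::local_tempfile()
  full <- readBin(path, "raw", n = file.size(path))
  writeBin(full[1:40], trunc)
  expect_error(load_kmer_bloom(trunc), "truncated")
  expect_error(load_kmer_bloom(tempfile()), "no such filter file")
})
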