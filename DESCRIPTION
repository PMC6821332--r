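Package: kmerpolish
Title: Alignment-Free Genome Assembly Polishing with k-mer Bloom Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Polishes draft genome assemblies without read alignment. Sequencing
    reads are streamed once to count canonical k-mers; coverage-thresholded
    ("solid") k-mers are stored in a Bloom filter sized for a target false
    positive rate, and each contig is then scanned 5' to 3' so that positions
    whose covering k-mers are absent from the filter can be repaired by base
    substitution or micro-insertion/deletion (up to 5 bp), governed by two
    leniency thresholds. Includes a synthetic-data generator (random genomes,
    mutated drafts, error-bearing reads) and a truth-based evaluator reporting
    recall and false discovery rate, so the whole pipeline can be exercised and
    benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    methods,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
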