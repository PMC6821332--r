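---
title: "Alignment-free assembly polishing with coverage-thresholded k-mer Bloom filters"
author: "kmerpolish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free assembly polishing with coverage-thresholded k-mer Bloom filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Draft genome assemblies carry residual base errors — substitutions and small
insertions/deletions — that downstream analyses inherit (frame shifts,
premature stops, spurious variants). The classical remedy is to align the
sequencing reads back to the draft and call corrections from pileups, which is
accurate but expensive at large genome sizes. `kmerpolish` takes the
alignment-free route: the only evidence it uses is whether each k-length word
(k-mer) of the draft occurs among the *solid* k-mers of the read set.

The pipeline has two halves.

**Filter building.** All reads are streamed once and every canonical k-mer
(the lexicographically smaller of a word and its reverse complement, making
evidence strand-independent) is counted exactly in a hash map. Sequencing
errors generate k-mers seen once or twice; genomic k-mers are seen about
coverage times. A coverage threshold `c_min` separates the two: only k-mers
with multiplicity ≥ `c_min` are kept. The surviving set is stored in a Bloom
filter — a bit array of `m = ⌈−n ln p / (ln 2)²⌉` bits probed by
`h = max(1, round(m/n · ln 2))` hash positions — which answers membership
queries with no false negatives and a tunable false-positive rate `p`
(default 5 × 10⁻⁴, small enough that spurious "present" calls cannot assemble
the ⌈k/y⌉ agreeing windows an edit needs). Double hashing (two independent
64-bit digests of the packed k-mer, combined as `g_i = h1 + i·h2 mod m`)
provides the `h` probe positions without `h` independent hash passes.

**Editing.** Each contig is scanned 5'→3'. While the draft is locally
correct, every window is present and the scan just advances. When a window is
absent, its 3'-end base comes under scrutiny — in a single-error model the
first absent window in scan order is exactly the one ending at the erroneous
base. Two *leniency factors* then govern the repair:

* **attempt** (`x`, default 5): an edit is attempted only when at least
  `⌈k/x⌉` of the k windows covering the base are absent;
* **accept** (`y`, default 9): a candidate change qualifies only when at
  least `⌈k/y⌉` of the windows containing the change are present.

Candidates are explored in a fixed order: the three alternate bases
(A < C < G < T), then deletions of 1..`max_indel` bases, then insertions of up
to `max_indel` bases (default and maximum 5 — the micro-indel regime; larger
events are structural and out of scope). Only homozygous errors are targeted:
at a heterozygous site both alleles' k-mers are typically solid, no window is
absent, and the scan passes by. This is by design — the method trades
allele-awareness for speed and memory.

## Scoring candidates, verifying edits

Three design points here are easy to get wrong, and each was chosen after
observing the corresponding failure mode on simulated data:

1. **Support counts windows containing the entire change** (for a deletion,
   the windows straddling the junction). The looser rule — any window
   touching a changed base — lets a 3-base insertion that merely *copies the
   upcoming genomic text* reach `⌈k/y⌉` support through windows ending inside
   the insertion; the scan would then happily transcribe the genome into the
   draft indefinitely. Under full containment a partial copy scores exactly
   one supporting window and never qualifies, while a genuine L-base
   insertion scores up to `k − L + 1`.

2. **Insertion candidates are enumerated as a prefix beam.** Lengths 1–2 are
   tried exhaustively (20 strings); a longer prefix is extended only if its
   *left-anchored window* (left flank + prefix, no 3' context) is present in
   the filter. Every prefix of a correct insertion passes this test, so the
   true candidate is never pruned, and the beam stays near-linear in
   `max_indel` instead of 4^5.

3. **Accepted edits are verified in place.** The winning candidate is applied
   tentatively and kept only if the site then stops triggering the attempt
   test (fewer than `⌈k/x⌉` covering windows absent). A correct repair turns
   every covering window back into a genomic k-mer, so it always passes
   (modulo the rare solid-k-mer dropout); an incidental qualifier — say, a
   single-base homopolymer extension at a junction whose out-of-register
   windows happen to match elsewhere — fails and is reverted. Candidates are
   tried in preference order until one verifies or all are exhausted. Without
   this step, a coincidentally-qualifying substitution at an indel junction
   shadows the correct insertion (about 4 % recall lost at 1 Mb), and
   certain homopolymer junctions never terminate.

Deterministic tie-breaking throughout: more support wins, then the shorter
edit, then deletions before insertions, then alphabetical bases. A repair
equivalent to the truth but placed differently (an indel shifted within a
homopolymer) yields the same sequence and is scored as correct by the
evaluator's sequence-restoration criterion.

Positions in the change log are 1-based on the *original* draft (maintained
through a running offset as indels shift coordinates), so the log can be
replayed onto the input by an independent tool; the VCF writer re-anchors
indels on the previous base per VCF convention and refuses to emit any record
whose REF disagrees with the draft.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 25 | word length (bases); 4–64 supported. Larger k brings more context (FDR falls) but needs more coverage per k-mer |
| `c_min` | `"auto"` | solid-k-mer threshold (multiplicity); `auto` takes the first local minimum of the multiplicity histogram, falling back to 2 when the histogram has no interior valley |
| `p_target` | 0.0005 | Bloom filter design FPR (dimensionless) |
| `x` | 5 | attempt leniency divisor: attempt when ≥ ⌈k/x⌉ covering windows absent |
| `y` | 9 | accept leniency divisor: accept when ≥ ⌈k/y⌉ containing windows present |
| `max_indel` | 5 | largest insertion/deletion repaired as one event (bases) |

Near contig ends (or next to non-ACGT runs) fewer than k windows exist; both
thresholds are computed on the windows actually available. Windows containing
any non-ACGT character are excluded from numerator and denominator alike —
they are neither presence nor absence evidence — and are never inserted into
a filter. Errors within the first k−1 bases of a contig are invisible to a
5'→3' scan (no window *ends* there) and are a known blind spot.

## What the synthetic data emulates — and what it does not

The generator provides the controlled conditions for benchmarking:
`random_genome()` draws i.i.d. bases at a chosen GC; `mutate_genome()` plants
substitutions and 1–5 bp indels at given per-base rates (binomial counts,
uniform indel lengths, insertions and deletions equally likely), recording
each event with both truth and draft coordinates so that replaying the truth
set reproduces the draft byte-for-byte; `simulate_reads()` draws
uniform-start, strand-balanced reads with substitution-only errors
(Illumina-like). Mutation sites are kept `min_spacing` apart and the same
distance from the sequence ends — isolated events a k-mer scan can see in
full, matching the controlled-benchmark setting (experiments here use
spacing `2k + 1`).

Real data differ in ways the generator deliberately ignores: repeats and
low-complexity tracts (a random 1 Mb sequence has essentially no exact
25-mer repeats, while real genomes do, and repeats are where k-mer evidence
is weakest), non-uniform coverage, clustered errors, heterozygosity, and
read indel errors. Passing the simulated benchmarks therefore demonstrates
the machinery is correct under the stated error model, not that real-genome
accuracy will match these numbers.

The evaluator scores an edit as a true positive only if an unmatched truth
mutation of the corresponding kind lies within a positional window (0 for
substitutions, 5 for indels) *and* applying the edit locally restores the
truth sequence — stricter than coordinate matching and immune to indel
placement ambiguity. Matching is greedy nearest-first; recall is
TP/(TP+FN), FDR is FP/(TP+FP) with 0 when no edits were made.

## Numerical and degenerate-input choices

* k is capped at 64 so a k-mer packs into 128 bits (two machine words); all
  published use of this method family sits at k ≤ 50.
* The multiplicity histogram's `auto` threshold is our own rule (the
  upstream tools do not publish one) and is intentionally the simplest thing
  that separates a bimodal histogram; `c_min` can always be fixed by hand.
* Contigs shorter than k pass through unedited (logged); an empty assembly
  yields empty outputs; a filter/editor k mismatch is an error, never a
  silent recompute.
* Filter files carry magic bytes, a format version and the full header
  (k, m, h, n_inserted, p_target); truncation or corruption is reported by
  field name.
* A safety valve aborts polishing with a warning if the edited contig grows
  past twice its input length — impossible under a sane filter, and cheap
  insurance against degenerate ones.
* All randomness flows through R's RNG (`set.seed()` reproduces everything,
  including the compiled read-error injection and FPR experiments).

## Validation scale

The test suite validates the editor against an exact k-mer set oracle (every
isolated error on ≤ 30 kb genomes reverted exactly, quiescence on re-polish,
leniency monotonicity), the Bloom filter against its design FPR, and the full
pipeline at the benchmark conditions: a 1 Mb genome, substitution and indel
rates of 10⁻³, 20× reads with 0.5 % base error at k = 25 (recall ≥ 97 % of
planted errors), and 30× at k = 45 (FDR ≤ 1 %). These sizes keep a full run
in minutes on one CPU while leaving the binomial noise on ~2000 planted
sites far smaller than the margins being tested. `scripts/acceptance.R`
re-runs exactly these experiments from scratch.

## Known limitations

* Homozygous errors only; allelic variants are neither called nor corrected.
* Micro-indels ≤ 5 bp per event; a 6 bp indel is left uncorrected (and, by
  the verification rule, not half-corrected either).
* Errors within k−1 bases of a contig end are not examined.
* Repeat-internal errors may lack absent-window signal (the flanking copies
  keep windows present) — the price of alignment-free evidence.
* The exact-counting filter builder holds the k-mer hash map in memory;
  it is sized for desk-scale experiments (tens of millions of k-mers), not
  for 20 Gb genomes.
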