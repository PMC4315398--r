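---
title: "Processing dual-indexed paired-end 16S amplicon runs with amplitag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing dual-indexed paired-end 16S amplicon runs with amplitag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplitag)
```

## The problem

Profiling a microbial community by 16S rRNA gene amplicon sequencing on a
paired-end instrument involves a long chain of processing decisions, each of
which silently discards reads: recognizing the sample barcodes on both mates,
merging the mates over their overlap, checking primers and base quality,
removing chimeric amplicons, clustering into OTUs and finally estimating
diversity. On real dual-indexed MiSeq runs roughly half of the raw read pairs
are lost along this chain, and a substantial fraction of pairs carry barcodes
from two *different* samples — a signature of inter-sample chimera formation
during pooled library preparation. `amplitag` implements this whole chain as
small, composable, testable functions, together with a ground-truthed
simulator, so that every stage's behaviour — and every loss — can be measured
rather than assumed.

## Barcode design

Sample tags are 7 bp sequences over ACGT prepended to the PCR primers
(defaults: Bakt_341F `CCTACGGGNGGCWGCAG` and Bakt_805R
`GACTACHVGGGTATCTAATCC`, targeting the V3–V4 region). `design_barcode_set()`
enumerates all k-mers and applies, in order:

1. **Homopolymer filter.** Runs of identical bases confuse base calling;
   "avoid homopolymers" is quantified as *no run longer than
   `max_homopolymer`* (default 2, i.e. no `AAA`). The threshold is
   configurable because there is no universally agreed cutoff.
2. **Minimum pairwise distance.** Every pair of distinct barcodes across
   both families must differ by at least `min_distance` substitutions
   (default 2). A greedy pass in lexicographic order retains a
   distance-separated subset; a maximum-clique search would yield more
   candidates but only feasibility matters here.
3. **Self-complementarity screen.** A barcode fused to a primer must not
   form hairpins or self-anneal. `screen_self_complementarity()` fails a
   construct containing a subsequence of length `min_stem` (default 6)
   whose reverse complement also occurs in the construct. Only *guaranteed*
   pairings count: a stem position pairs with its partner only when both
   symbols are concrete ACGT and complementary. Degenerate primer positions
   (mixed-base synthesis, e.g. `W` = A or T) are excluded from stems
   deliberately — under set-intersection semantics the published primers
   would fail their own screen (`CWGCAG` "pairs" with itself when `W` is
   read as A in one copy and T in the other), yet they are validated,
   field-standard primers. The screen is a sequence-level proxy for the
   thermodynamic tools (Primer3, BLASTN) a wet lab would also run.
4. **Random draw.** `n_pairs` forward and `n_pairs` reverse barcodes are
   drawn from the surviving pool with a fixed seed. The two pools are
   disjoint so that family membership is unambiguous during demultiplexing.

Exceeding the candidate capacity at any stage raises an error naming the
failed constraint (e.g. 4^4 = 256 4-mers cannot yield 10,000 pairs).

## Demultiplexing: five categories

`classify_read_pair()` inspects the first `L` bases of each mate for an
exact, anchored match to any barcode and assigns exactly one category:
`MATCHED`, `NO_BARCODE`, `ONE_BARCODE`, `SAME_FAMILY` (two forward or two
reverse barcodes) or `CROSS_SAMPLE` (a forward and a reverse barcode from
different samples). Design choices:

* **Exact matching only.** With minimum pairwise distance 2, one sequencing
  error is detectable but not unambiguously correctable, so no mismatch
  tolerance is offered.
* **Both orientations accepted.** Library preparation does not fix the
  amplicon orientation, so the forward barcode may sit on either mate; the
  orientation is recorded and MATCHED output is standardized to
  forward-first with the `L` barcode bases trimmed. Primer removal is
  deferred to QC.

The five category counts always partition the input — an invariant asserted
throughout the test suite. `demultiplex_run()` additionally reports per-sample
yields (with their relative standard deviation) and the ordered
barcode-pair count table that feeds the crossover diagnostic below.

## Assembly

`merge_pairs()` reverse-complements the reverse mate and scans every ungapped
suffix/prefix overlap between `min_overlap` (default 10 bp; real V3–V4
overlaps are mostly 20–70 bp) and `max_overlap`, keeping the overlap that
maximizes matches − mismatches (ties to the longer overlap). The assembly
score is the identity fraction of that overlap, and pairs scoring below 0.6 —
short alignments or a high proportion of mismatches — are rejected as
`low_quality`. When even the best candidate mismatches at more positions than
it matches, the pair is `unassembled`: there is no credible overlap. The
consensus takes the higher-PHRED base at disagreeing positions (ties to
mate 1), with quality max at agreements and min at disagreements; these rules
are fixed here for determinism. The alignment is ungapped on purpose:
substitutions dominate the error profile of the instrument, and an indel in
the overlap is itself grounds for rejection.

## Quality control

`apply_qc()` applies four filters in a fixed order — forward primer at the
start and reverse primer (reverse-complemented) at the end, IUPAC-aware with
0 mismatches, then trimmed; no undetermined (`N`) bases; no 10 bp sliding
window with mean PHRED below 5; assembly overlap no longer than 100 bp. Each
read is charged to the *first* filter it fails, so the per-filter counts are
disjoint and partition the batch. Two readings of the window rule are
possible (window mean vs window minimum); the mean is adopted and both the
window width and threshold are configurable. The filter order is fixed; the
survivor *set* would differ under reordering, which is why the ledger tests
assert cascade accounting rather than order invariance.

## Crossover and chimera diagnostics

Two complementary diagnostics target inter-sample chimera formation:

* **Mismatch regression.** For every ordered pair of distinct barcodes
  (excluding self-pairs and correct pairings — `B² − 2B` points for `B`
  barcodes), `mismatch_regression_points()` plots the share of mismatches
  involving the second barcode against the relative yield of the first. If
  crossovers arise uniformly from amplicon abundance, points fall on a
  line; `flag_crossover_outliers()` fits it by least squares and flags
  points beyond 3 residual standard deviations (the multiplier is
  configurable; no published cutoff exists). "Mismatches involving" a
  barcode counts pairs where it appears in either position.
* **De novo chimera scan.** `denovo_chimera_scan()` implements a
  deliberately simple two-parent breakpoint model: a dereplicated query is
  chimeric when some breakpoint splits it into a prefix and a suffix that
  each match a distinct parent at ≥ 99% identity (ungapped, ≥ 30 bp), with
  both parents at least twice as abundant as the query. A query ≥ 99%
  identical to a single more abundant parent over its full length is a
  point mutant, not a chimera. Three-parent chimeras and reference-database
  modes are out of scope; the simple model is sufficient to measure
  recall/false-positive behaviour against simulated ground truth.

## Clustering

`greedy_otu_cluster()` scans dereplicated sequences in decreasing abundance
order; each joins the first centroid at ≥ 97% identity or founds a new one
(a minimum difference of 3% between cluster centers). One greedy
implementation with a configurable threshold stands in for the family of
published heuristics, whose alpha- and beta-diversity trends are known to be
conserved. Identity is the fraction of matching columns of a global end-free
alignment computed by banded dynamic programming (match +1, mismatch −1,
gap −2; ties diagonal > up > left). The nominal band half-width is 16 —
V3–V4 length variation is small — and widens automatically to the length
difference + 8, since a narrower band cannot reach the opposite corner of
the matrix. The band has a second, intended effect: it restricts the
alignment to near-global paths, so two sequences sharing only a short
terminal word cannot claim a high "identity" over a tiny core. An 8-mer
prescreen skips the alignment for centroid pairs that cannot possibly reach
the threshold (applied only when both sequences are ≥ 64 bp; a ≥ 97%
match of that size must share far more than the 8 distinct 8-mers
required). With `discard_singletons`, size-1 sequences may join centroids
but never found them — the convention of abundance-greedy pipelines.

`trim_to_length()` harmonizes reads from platforms with different read
lengths by keeping the first 400 bp and *discarding* shorter reads — padding
would fabricate bases. `bin_length_fractions()` splits amplicons at 446 and
464 bp into the three length classes observed for V3–V4 (the short class is
archaeal in origin).

## Diversity statistics

All estimators work on plain samples × OTUs count matrices:

* **Chao1** uses the classic form `S_obs + F1²/(2 F2)`, falling back to
  `S_obs + F1(F1−1)/2` when no doubletons exist. This is *not* the
  bias-corrected variant some packages report; the classic form is the
  stated estimator here, and the test suite pins it by closed-form cases.
* **ACE** uses the abundance-based coverage estimator with the rare class
  at abundance ≤ 10, and is undefined (NA) when the rare class consists
  entirely of singletons; it agrees with `vegan::estimateR` to numerical
  precision, which the tests verify as an independent cross-check.
* **Shannon** (natural log), **Simpson** as `1 − Σ p²` (near 1 for even
  communities) and **Pielou** `H / ln S` (undefined for one species).
* **Bray–Curtis** after square-root transform and Wisconsin double
  standardization (each OTU by its maximum, each sample by its total),
  intended for rarefied tables. "Square transformation" is read as square
  root — the standard companion of Wisconsin standardization in community
  ecology — and the transform is configurable to identity.
* **Weighted UniFrac** over a rooted tree: `Σ l_b |p_A(b) − p_B(b)|`,
  normalized by `Σ l_b (p_A(b) + p_B(b))` by default so values are
  comparable across trees and lie in [0, 1]; the raw variant is available.
* **UPGMA** via average-linkage `hclust`, returned as an `ape` tree;
  ultrametric inputs are reconstructed exactly.
* **Rarefaction** subsamples each sample without replacement to a fixed
  depth (default the smallest sample), dropping — with a warning — samples
  below it, since depth-sensitive estimators cannot be computed for them.
* **PERMANOVA** partitions squared distances (pseudo-F and R²; verified
  against `vegan::adonis2` in the tests), **permutational ANOVA** does the
  univariate analogue, and the **Mantel test** correlates two distance
  matrices. All permutation p-values use `(1 + b)/(1 + m)` so p = 0 is
  never reported. With `g` groups of equal size `k`, label permutations
  that reproduce the observed partition tie with the observed statistic,
  so the attainable p-value floor is about `(1 + E[ties])/(1 + m)`; power
  checks therefore use groups of ≥ 10.
* **Occupancy accumulation** sums the reads of OTUs present in at least X%
  of samples for X = 0..100; the curve is non-increasing with the grand
  total at X = 0.

## The simulator

`build_mock_community()` + `simulate_run()` generate a dual-indexed run with
exact per-read ground truth (sample, taxon, demultiplexing category, chimera
status). What it emulates, and the corresponding defaults:

* **Uneven yields**: per-sample depths are log-normal with relative
  standard deviation `depth_rsd = 0.55`, the upper end of what real
  dual-indexed runs show.
* **Length classes**: amplicons (primers included) are drawn in three
  classes — ≤ 446, 447–464, ≥ 465 bp (capped at 476 so 2×250 mates always
  overlap by ≥ 10 bp) — with a default mix of 15/55/30%, a qualitative
  match to the observed trimodal length distribution. Inserts are random
  DNA, which makes taxa mutually far more than 3% divergent by
  construction.
* **Quality decay**: position-dependent PHRED profiles average ~36 on the
  forward and ~33 on the reverse mate, declining toward the 3' end; a
  `degraded_fraction` (default 2%) of pairs carries a quality-crashed
  reverse tail. Substitution errors are drawn with exactly the probability
  implied by the emitted quality (`10^(-Q/10)`), so quality filters act on
  honest signal. The model is substitution-only — the dominant error mode
  of the instrument, and the assembler is ungapped. Undetermined bases
  appear at `n_rate` (default 5e-6 per base).
* **Barcode corruption**: errors never hit the 7 bp barcode region;
  mis-assignment is controlled exclusively by `crossover_rate` (the pair's
  second tag is swapped for another barcode — the library-preparation
  crossover mechanism, applied at the read-pair level rather than modelling
  polymerase mechanics), `no_barcode_fraction` and `one_barcode_fraction`
  (tags overwritten with random non-barcode 7-mers). This separation makes
  the recorded ground-truth category of every pair exact.
* **Chimeras**: with probability `chimera_rate` the amplicon is a splice of
  two parents drawn by abundance, at a breakpoint uniform over the interior
  with a 50 bp margin on both sides — a partial extension product must
  anneal to its second template over a minimal stretch, so breakpoints
  within a few dozen bases of an end are not productive.

What it does **not** emulate: indels, flow-cell artifacts, PhiX
(unrecognized tags are random DNA), taxonomically structured sequence
similarity between taxa, or PCR abundance biases. Tests passing on simulated
runs therefore demonstrate the pipeline's bookkeeping, thresholds and
recovery behaviour under the stated error model — not robustness to, e.g.,
indel-rich platforms or closely related natural taxa straddling the 97%
boundary.

## The loss ledger

`run_pipeline()` chains demultiplex → assembly → QC → (optional) chimera
removal → clustering → diversity, with all thresholds defaulting to the
protocol values (score 0.6, window 10 at Q5, overlap ≤ 100 bp, identity
0.97), and maintains a `loss_ledger`: at every step
`reads_out + reads_removed = reads_in`, consecutive steps chain, and every
removal is attributed to exactly one reason. `validate_ledger()` asserts
these invariants and is run after every pipeline test. `render_report()`
turns ledger + category counts into the category percentages, per-barcode
RSD, per-filter losses and cumulative retention, as printable output or
JSON.

## Worked example

```{r example}
bs <- design_barcode_set(10, length = 7, min_distance = 2,
                         max_homopolymer = 2, seed = 42)
comm <- build_mock_community(20, seed = 7)
cfg <- run_config(mean_depth = 300, crossover_rate = 0.05,
                  chimera_rate = 0.02, seed = 3)
run <- simulate_run(comm, bs, cfg)
res <- run_pipeline(run, bs, chimera_check = TRUE, seed = 5)
res$ledger
head(res$alpha, 3)
```

Problem sizes throughout the examples and tests (tens of samples, a few
hundred to a few thousand pairs per sample, 10–50 taxa) are chosen so a
complete run takes seconds on a laptop while still exercising every failure
mode; all operating points (thresholds, rates) are the protocol defaults.

## Command line

A thin front end over the same functions is installed at
`system.file("scripts", "amplitag", package = "amplitag")`, with subcommands
`design-barcodes`, `simulate`, `demux`, `assemble`, `qc`, `chimera`,
`cluster`, `diversity`, `run` and `report`. Stages exchange standard
formats: FASTQ for reads, TSV for barcode maps, assignments, OTU tables and
distance matrices, Newick for trees, JSON for reports.

## Known limitations

* Exact barcode matching cannot rescue pairs with a single sequencing error
  in the tag (by design, given distance-2 sets).
* The identity-fraction assembly score approximates, but is not identical
  to, probabilistic overlap scores used by other merge tools; the 0.6
  cutoff keeps the same semantics (short or mismatch-rich overlaps fail).
* The chimera scan's two-parent, 99%-segment model will miss chimeras whose
  breakpoint lies within 30 bp of an end and chimeras of more than two
  parents.
* Greedy clustering is input-order dependent by construction (abundance
  presorting makes it deterministic) and, like all single-linkage-to-
  centroid heuristics, can split clusters whose members straddle the
  radius.
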