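---
title: "Methods: structural-genomic analysis of radiation-induced glioma cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural-genomic analysis of radiation-induced glioma cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rigstruct)
```

## Scope and data model

`rigstruct` implements the desk-scale structural-genomics computations used
in cohort studies of pediatric radiation-induced high-grade glioma (RIG):
classification of copy-number (CN) segments, chromothripsis inference,
reconstruction of extrachromosomal circular DNA (eccDNA) amplicons,
mutation-load comparison between tumor subgroups, and the patient-level
statistics layer. Upstream primary analysis (read mapping, variant and SV
calling, methylation array processing) is out of scope; the package starts
from the standard text artifacts those tools emit:

* **SEG** segmentation tables (IGV dialect, 1-based inclusive on disk;
  0-based half-open in memory) — one row per sample x interval with a mean
  log2 copy ratio (`seg_mean`),
* **BEDPE** structural-variant breakpoint pairs with strands, from which
  the join orientation class (deletion-type `+/-`, duplication-type `-/+`,
  head-to-head `+/+`, tail-to-tail `-/-`) is derived,
* **VCF 4.2** small-variant calls with QUAL and AD-style allele depths,
* a **clinical TSV** mirroring the printed per-case summary table (dash =
  missing).

All coordinate conversions are centralized in the IO layer, and every
reader/writer pair round-trips exactly.

## Copy-number classification

Direction is called from the mean log2 ratio with *inclusive* thresholds:
gain at `seg_mean >= 0.2`, loss at `<= -0.2` (the methylation-array rule;
a `wgs` preset uses ±0.25, the reporting rule of paired tumor–germline CN
callers). The sources state the thresholds without strictness; inclusive
boundaries make behavior at exactly ±0.2 deterministic.

Extent has two published phrasings — "≤ 25% of the chromosome arm" and
"focal (≤ 3 Mb)" — and it is not recorded which governed each printed
call. Both are implemented (`focal_mode = "arm25"` default, `"3mb"`
alternative) and neither is asserted as canonical. Segments spanning the
centromere are split there first, so the arm fraction is always well
defined; both halves inherit the segment mean and hence the direction.

Gene-level calls take the overlapping segment with maximal `|seg_mean|` —
a deterministic stand-in for the manual, cross-platform adjudication used
in practice. Amplification begins at log2 ratio 2.0 (about eight copies on
a diploid background); the sources say only "highly amplified", so the
cutoff is configurable.

## Chromothripsis inference

Chromothripsis — a single catastrophic shattering-and-religation event —
is inferred per chromosome from four hallmarks, and called when **at least
two** are satisfied. The hallmark list is standard; its statistical forms
are not published for this analysis, so the package commits to concrete,
oracle-testable forms:

* **C1, CN oscillation.** Integer states are `round(2 * 2^seg_mean)` on a
  diploid baseline. Satisfied when the two most frequent states cover at
  least 80% of segments *and* the state sequence switches between them at
  least 6 times. Requires ≥ 10 segments.
* **C2, breakpoint clustering.** A Monte-Carlo spacing test against
  uniform placement of the same number of breakpoints on the same
  chromosome. The statistic is a one-sided KS-type *excess of small
  spacings*: spacings are probability-transformed through the exact null
  spacing CDF (`Beta(1, n-1)` scaled by chromosome length) and the maximal
  excess of the empirical CDF over uniform is taken only over the lower
  half of the null distribution. The restriction matters: a plain KS
  distance also fires for *over-regular* spacing (a deficit of small
  spacings), which is the opposite of clustering. With the restricted
  statistic, exactly equally spaced breakpoints score zero and can never
  be called clustered. 1000 seeded resamples by default; ≥ 10 breakpoints
  required.
* **C3, join randomness.** Goodness of fit of the four orientation-class
  counts against equal quarters: chi-square (df 3) at ≥ 8 joins, an exact
  multinomial sum at 4–7, not evaluable below 4.
* **C4, order randomness.** The statistic is the Spearman correlation
  between each join's left (smaller) breakend and its partner breakend.
  The naive correlation test is *structurally* miscalibrated here: the
  smaller and larger member of any random pair are positively correlated,
  and the plain test rejects roughly 40% of truly random religations. The
  p-value is therefore computed conditionally on the observed breakend
  positions by re-pairing them at random (seeded Monte-Carlo) — exact
  under the random-religation null by construction, and sensitive to the
  ordered, short-range pairing left by sequential rearrangement.
  Requires ≥ 8 joins.

C3 and C4 invert the usual test logic: chromothripsis *predicts*
randomness, so those criteria are satisfied when the test does **not**
reject (p ≥ α). α = 0.05 per criterion with no multiplicity correction —
the ≥ 2-of-4 rule is the published combiner. Non-evaluable criteria count
as not satisfied. A call resting on exactly two criteria carries a
`borderline` flag, the reproducible stand-in for "further evaluated by
manual review". Cohort frequencies are compared with a one-sided Fisher
exact test, matching the published comparison direction.

## eccDNA reconstruction

Candidate eccDNA structures are cycles over highly amplified segments
connected by SV adjacencies. Segments at or above the amplification
threshold become nodes with a left and a right end; a join becomes an edge
when each breakend lies within a tolerance (default 10 kb — segmentation
and breakpoint calls differ in resolution) of a matching boundary, with
the strand selecting the end (`+` → right, `-` → left). Cycles are
enumerated exhaustively (depth-first, ≤ 20 nodes) under the
traverse-through constraint — every segment is entered at one end and
exited at the other — deduplicated under rotation and reversal by
anchoring at the smallest node id in forward orientation, and ranked by
total amplified mass (Σ length × 2^seg_mean). Only closed cycles are
reported; linear amplicon paths are not, because the object of interest
is circular. An independent verifier re-walks every reported cycle
directly against the raw joins.

## Mutation load

Two deliberately different filters, reflecting how germline and somatic
call sets fail differently:

* **Germline load**: calls with `QUAL >= 50` (inclusive), read support
  ignored.
* **Somatic load**: calls with at least 4 supporting reads, QUAL ignored —
  subclonal variants in heterogeneous tumors are real yet low-QUAL.
* **Exome reporting filter**: ≥ 5 mutant alleles *and* ≥ 30% VAF, with a
  curated-database match bypass.

Loads are normalized per Mb over a configurable coding-space size
(default 34 Mb — a scalar, so no annotation dependency at desk scale).
Substitution spectra use the 6-class purine/pyrimidine-collapsed naming
(A>C, A>G, A>T, C>A, C>G, C>T); T- and G-reference substitutions are
reverse-complemented into the A/C-reference classes. Group comparison:
fold change of means (B/A), two-sided Welch t-test on loads, chi-square on
pooled spectrum counts. Hypermutators (somatic rate > 10/Mb, or an
explicit id list mirroring the exclusion of a known mismatch-repair-
deficient case) are excluded by default.

## The synthetic cohort: a stated world

The generator (`sim_config()`, `simulate_cohort()`) plants the exact
structure the callers test for, with ground truth retained, so the whole
pipeline is validated by planted-truth recovery rather than by
re-analysis of controlled-access data. Defaults encode the cohort the
analysis was designed around:

* 3 Group A and 6 Group B tumors with paired germline data; somatic rate
  0.3/Mb in Group A and **9×** that in Group B; identical germline rates
  (30/Mb over the 34 Mb coding space — coding-space-restricted for
  artifact size, which scales both groups equally).
* Chromothripsis: 30 breakpoints uniform inside a window spanning 10% of
  the chromosome; fragments independently retained (log2 ≈ 0) or lost
  (log2 ≈ −1, one copy on diploid) with probability 0.5; retained
  fragments shuffled and randomly oriented; joins are the derivative
  adjacencies. Segment-mean jitter sd 0.05 gives clean two-state
  oscillation with realistic noise.
* Progressive controls: 8 sequential deletion/duplication events of
  1–20 Mb, giving nested multi-state profiles and ordered joins.
* eccDNA: 2–5 disjoint fragments of 0.1–1 Mb at log2 2.5; noise on the
  planted amplification is truncated upward so the configured level is a
  guaranteed floor (otherwise a fragment planted exactly at the threshold
  would fail selection half the time by construction).
* Clinical tables: log-normal ages (median 7 y) and latencies (median
  8 y), exponential survival (median 9 months), ~19% unknown vital
  status, missingness marked with dashes.

One RNG stream per sample is derived from the master seed, so per-sample
outputs are independent of generation order, and every `simulate_*`
function is byte-identical under a repeated seed.

What a green recovery test does *not* establish: the generator draws
breakpoints uniformly within one window (real chromothripsis can be
multi-region), uses a single noise scale, ignores trinucleotide mutation
context and mappability, and its progressive control is one specific
alternative process. Recovery numbers are statements about this stated
world, not clinical performance claims.

## Numerical choices and edge cases

* All threshold comparisons are inclusive; ties in boundary matching go to
  the lower coordinate with a warning.
* Fisher's exact test uses the conventional two-sided rule (sum of all
  fixed-margin tables no more probable than the observed one), which
  reproduces both published contingency p-values; a zero margin returns
  p = 1 with a `degenerate` flag. A note on one-sided tests: for two
  identical cohorts the upper-tail p is large but not exactly 1 (it
  includes the probability of the observed table itself); the test suite
  asserts p ≥ 0.5 there rather than the idealized 1.
* Odds-ratio CIs use the log-normal approximation with Haldane–Anscombe
  0.5 correction when any cell is zero; a double-zero diagonal is flagged
  undefined rather than guessed.
* The Kaplan–Meier median is the smallest time with S(t) ≤ 0.5; its CI is
  the Brookmeyer–Crowley inversion of the log-transformed Greenwood
  pointwise band (the estimator is named in the sources, the CI method is
  not — this is the common default, and the implementation is
  cross-checked against `survival::survfit`).
* Monte-Carlo p-values use the add-one estimator `(1 + #{T_null ≥ T_obs})
  / (B + 1)`, so they are never exactly zero.
* Copy-number state 0 segments in the progressive generator are emitted at
  log2 −3 (a deep-loss cap) rather than −∞.

## Known limitations

* The chromothripsis criteria operate per chromosome and do not model
  inter-chromosomal shattering; interchromosomal joins contribute to no
  criterion.
* Cycle enumeration is exhaustive and intended for desk-scale amplicon
  graphs (≤ 20 amplified segments); larger graphs need a raised
  amplification threshold rather than a heuristic decomposition.
* The QUAL-threshold sensitivity analysis mentioned alongside the load
  filters has no published procedure; the thresholds are exposed as
  configuration, with the published values as defaults.
* Published cohort-level results that require the deposited sequencing
  data (per-case chromothripsis criteria, eccDNA coordinates) cannot be
  reproduced at desk scale; the test suite substitutes planted-truth
  recovery with explicit targets (sensitivity ≥ 0.9, false-positive rate
  ≤ 0.1, eccDNA recovery ≥ 95%, planted fold within ±20%), computed by
  `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.
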