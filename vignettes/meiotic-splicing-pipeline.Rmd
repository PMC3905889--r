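---
title: "Methods: sequence analysis of meiotically regulated alternative splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence analysis of meiotically regulated alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiosplice)
```

## The biological question and the computational model

During the first synchronous wave of mouse spermatogenesis the testis moves
from a pre-meiotic state (6 days post partum, dpp) to one dominated by
meiotic spermatocytes (21 dpp). This transition rewires alternative
splicing: a set of cassette exons gains inclusion (activated), another set
loses it (repressed), and the expression of RNA-binding splicing regulators
— notably the switch from PTBP1 to its neural/germline paralogue PTBP2 —
shifts at the same time. `meiosplice` implements the downstream sequence
analysis of that system as a reusable, fully tested pipeline:

1. **Event catalog** — partition a table of splicing events, scored by a
   Bayes factor from an upstream inference tool, into activated, repressed
   and background sets.
2. **Context extraction** — obtain the transcript-sense sequence of each
   exon plus up to 250 nt of each flanking intron.
3. **5-mer enrichment** — compare word frequencies between a regulated set
   and the background set, region by region.
4. **PTB site scanning** — enumerate combinatorial arrangements of a spaced
   pyrimidine motif at two stringencies.
5. **PSI quantitation and clustering** — percent-spliced-in values from
   isoform signals, assembled into an events-by-samples matrix and
   clustered hierarchically.
6. **Expression landscape** — length-normalised fold-change flags for
   splicing-regulator genes and the consensus intersection of two
   differential-expression caller lists.

Bayes factors are always *consumed as input scores*, never computed: the
upstream Bayesian inference (and read alignment, counting, and the internal
statistics of differential-expression callers) is out of scope.

## Event classification

An event enters the **regulated** tier when its Bayes factor is strictly
above 10 and its exon is at most 500 nt long (over-length exons are
excluded from both tiers); direction is decided by the sign of
`psi_stage_b - psi_stage_a` (meiotic minus pre-meiotic): positive is
activated, negative repressed. Ties give no direction, and a regulated-tier
event missing a stage PSI is left unassigned with a warning, never guessed.
The **background** — expressed but not differentially spliced — requires a
Bayes factor strictly below 0.1 and the same length bound. Values exactly
at a threshold fall in neither tier: the cut-offs are stated as strict
inequalities and are implemented that way. The partition is always disjoint
and exhaustive, and the regulated count is monotone non-increasing in the
Bayes-factor cut-off; both properties are enforced by tests.

## Context extraction

Sequences are handled 0-based half-open internally (BED convention on
disk); the parser converts 1-based inclusive dialects on entry. For a
plus-strand exon `[s, e)` the upstream flank is `[s - 250, s)` and the
downstream flank `[e, e + 250)`; for minus-strand events the genomic
windows are mirrored and all three sequences reverse-complemented, so
"upstream" is always 5' of the exon in the pre-mRNA. Two deliberate
choices:

* Flanks shorter than 250 nt (chromosome edge, or a neighbouring exon when
  `neighbor_bounds` clipping is requested) are **truncated, never padded**
  — padding would dilute k-mer frequencies with invented sequence. The
  truncation is flagged per side. Neighbour clipping is supported but off
  by default.
* Soft-masked (lower-case) genome bases are uppercased and retained;
  discarding repeats would make frequencies incomparable with genome-wide
  counts.

## 5-mer enrichment

All `4^5 = 1024` words are counted in one region of every context with a
sliding window of stride 1; windows containing `N` are skipped and do not
enter the window total, so frequencies are always relative to informative
windows. Counts are pooled per set and normalised to the set's total
window count — the "frequency" normalisation to data-set size — and words
are ranked by `delta = freq_test - freq_bg`, the *difference* to
background, with lexicographic tie-break and dense ranks. A frequency
ratio is reported alongside but never used for ranking. Regions are
counted independently; a word never spans a region boundary
(`region = "all"` pools the three per-region counts, still without
boundary-spanning windows).

Significance is a **Welch two-sample t-test on per-sequence frequencies**
(test set vs background, two-sided). This is the only construction of a
"t-test on k-mer enrichment" that uses the replication actually available
— the sequences. When both per-sequence frequency samples are constant the
statistic is undefined and reported as `NA` with p = 1. No multiple-testing
correction is applied by default (the ranked list is descriptive); a
Benjamini–Hochberg column is available via `p_adjust = TRUE`.

The RBP annotation layer (`annotate_kmers()`) is deliberately heuristic:
pyrimidine CU-rich words are labelled PTB, GAA-core words Tra2beta,
UAAA-like words Sam68/T-STAR, UG repeats CELF and YGCY MBNL. Labels alter
no statistics.

## The combinatorial PTB scanner

PTB recognises short pyrimidine elements through multiple RRM domains with
flexible spacing. The scanner's pattern is three specified blocks,
`YCU … CU … YCU` (`Y` = C or U, 8 specified nucleotides), separated by two
spacers:

| preset | spacer 1 | spacer 2 | mismatch budget |
|--------|----------|----------|-----------------|
| high   | 1–6 nt   | 1–8 nt   | 0               |
| low    | 1–6 nt   | 3–8 nt   | 1 (i.e. 7 of 8 specified nt) |

Each distinct `(start, spacer1, spacer2)` triple whose specified positions
fit within the mismatch budget is one **arrangement** — one binding
possibility. Arrangements may overlap and share starts. Decisions worth
recording:

* The low-stringency second spacer range (3–8) genuinely differs from the
  high-stringency one (1–8); both are implemented exactly as defined, so
  the presets are *not* fully nested — only high-preset matches with
  spacer 2 in 3–8 reappear in the low preset (a property test checks
  exactly this partial nesting).
* The mismatch budget is **global over the 8 specified positions**, not
  per block.
* `N` at a specified position always counts as a mismatch (conservative
  for masked/unknown bases); `N` in a spacer is free. `T` is accepted on
  input and normalised to `U`. Scanning is single-strand, transcript-sense.
* Per-position profiles come in two modes because a published per-position
  y-axis can be built either way: `starts` (arrangements beginning at each
  position; sums to the match count) and `coverage` (arrangements whose
  footprint covers each position; the default for figure-like output).
* `scan_context()` scans the concatenation upstream + exon + downstream so
  arrangements straddling a boundary are found once, labelled by the
  region of their start.

Correctness is established against an independent enumerator built from
fixed-length lookahead regular expressions — a different mechanism from
the scanner's vectorised per-offset comparison — with exact set equality
of `(start, spacer1, spacer2, mismatches)` tuples on 1000 seeded random
sequences plus hand-worked cases.

## PSI quantitation and clustering

`PSI = 100 * inclusion / (inclusion + exclusion)`; a measurement with both
signals zero carries no PSI and is `NA`. The matrix builder requires
unique (event, sample) pairs and leaves absent pairs missing.

The clustering procedure is fixed as agglomerative hierarchical clustering
with Euclidean distance and average linkage, applied independently to rows
and columns. Because dendrogram tie-breaks depend on input order, rows and
columns are sorted lexicographically by name before distances are
computed: the result is deterministic and invariant to input permutation.
Clustering needs a complete matrix; the default handling of missing cells
is to drop incomplete rows (no imputation model is assumed), with
row-mean imputation available as an explicit option.

## Expression landscape

Raw counts are divided by feature length (counts per nt); the fold change
is the larger normalised value over the smaller, and genes reaching the
threshold (default 2) are flagged by direction. A gene detected at one
stage only has an infinite fold change and is flagged, not rejected — such
genes are real points on a two-stage scatter. The consensus
differentially-expressed set is the exact intersection of two caller
lists, preserving the first list's order.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with complete
ground truth, under a single mandatory seed (per-stream sub-seeds make the
four artifact families — contexts, events, measurements, expression —
independently regenerable). Its defaults *are* the study conditions: 159
activated, 92 repressed, 276 background contexts and events; 250 nt
flanks; 9 over-length decoy events; Bayes factors drawn log-uniformly from
[12, 1000] (regulated) and [0.001, 0.08] (background), ranges chosen
strictly clear of the 10/0.1 thresholds so that a planted partition is
recoverable exactly; PSI noise sd 5 percent. Exon lengths default to
60–300 nt — typical cassette-exon scale, safely below the 500 nt filter —
and decoys to 501–800 nt.

Sequences are i.i.d. draws from a configurable base composition (default
uniform). This null has no dinucleotide structure, splice-site signal, or
compositional gradient; that is acceptable here because the enrichment
analysis is background-controlled — both sets share the null — so tests on
synthetic data demonstrate *recovery of planted signal over a matched
background*, not performance on real genomic sequence. Motif spikes
**replace** bases at uniform random non-overlapping positions (rejection
sampling with a bound, then an error), keeping sequence length and window
counts constant so spiked and unspiked sets remain directly comparable.
Isoform signals are built by adding Gaussian noise (sd = `psi_noise_sd`/100)
to the true inclusion fraction, truncating to [0, 1], and splitting a
random total signal accordingly: with zero noise the PSI formula recovers
truth exactly; with noise the mean over n replicates obeys the usual
`3·sd/sqrt(n)` bound, which is what the tests assert.

For the spike-and-recover check the expected excess frequency of the
planted word is computed in closed form under the i.i.d. model (exact
enumeration over spike positions and overlapping windows, including the
self-overlap structure of the word), and the measured delta is required to
fall within three standard errors of it.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the study's set sizes
(159/92/276 contexts with 250 nt flanks; 536-row event tables; 1000-gene
expression tables; 1000 random sequences up to 200 nt for the
scanner-oracle comparison) — small enough to complete in well under a
minute each on one core, large enough that every planted signal is
recovered with wide margins. Frequency sums are checked to 1e-12;
PSI recovery without noise to 1e-9 (floating-point arithmetic only);
equality of scanner and enumerator is exact, not approximate.

## Known limitations

* The i.i.d. sequence null ignores real intron composition (pyrimidine
  gradients near 3' splice sites would elevate CU-rich counts in both
  sets); conclusions about real data must come from real backgrounds.
* The scanner models arrangement counts, not binding affinity or
  occupancy; no thermodynamic scoring is attempted, and the two presets
  are stringency tiers, not a graded affinity scale.
* The t-test treats per-sequence frequencies as approximately normal;
  for rare words at short sequence lengths this is coarse, which is one
  reason ranking is by frequency difference rather than by p-value.
* PSI from two isoform signals assumes the two isoforms amplify/quantify
  with equal efficiency; no correction for amplification bias is made.
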