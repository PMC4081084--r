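---
title: "Methods: peak annotation, stratification, motif census and co-occupancy"
author: "peakscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak annotation, stratification, motif census and co-occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakscape)
```

## The model

`peakscape` treats a ChIP-seq experiment, post peak calling, as a set of
genomic intervals with optional summits, and asks how those intervals
relate to a strand-aware gene annotation, to gene expression, to
core-promoter sequence elements, and to other occupancy tracks. The
coordinate model is uniformly 0-based half-open (BED convention); GTF input
is shifted at the boundary. The TSS of a `+` gene is its span start; for a
`-` gene it is the last base of the span (`span_end - 1`), the standard
convention, and the TES is the opposite terminus.

Every distance is anchored at a peak's *reference point*: the summit when
the peak caller reported one, otherwise the floored interval midpoint.
Summits are the most specific localisation a peak caller provides, which is
why they are the default anchor; a midpoint-only analysis falls out
automatically for BED input without summits. The signed TSS distance is
read in the gene's reading direction (negative upstream, positive
downstream), so upstream/downstream claims are strand-aware by
construction.

"Nearest gene" means nearest by absolute signed TSS distance, not by gene
body overlap — the same reference frame the distance statistics use. Ties
are broken by the lexicographically smallest gene id, which makes
assignment deterministic and independent of input order; peaks on
chromosomes without genes are reported `unassigned` rather than dropped.

## Tunable parameters

All thresholds are arguments with the analysis' standard values as
defaults, and every run logs them into its report:

| parameter | default | meaning |
|---|---|---|
| `proximal_threshold` | 1000 bp | proximal iff \|d\| ≤ threshold (inclusive: "±1 kb" reads as a closed interval) |
| `profile_window`, `profile_bin` | 2000, 100 bp | TSS-distance histogram range and bin width |
| `motif_width` | 75 nt | summit-centered window, total width (±37 around the summit) |
| `tss_limit` | 1000 bp | census restricted to peaks within this TSS distance |
| `flag_distance` | 10 kb | peaks farther than this from any TSS are flagged (motif input restriction) |
| `rpkm_cutoff` | 1 | expressed iff RPKM ≥ cutoff (inclusive boundary) |
| `maxgap` | 150 nt | co-occupancy edge-gap tolerance, boundary inclusive |

Three boundary conventions deserve explicit statement because no external
definition pins them down. First, the RPKM boundary is inclusive: a gene at
exactly the cutoff is expressed. Second, a proximal peak at signed distance
exactly 0 counts as *downstream* — transcription initiates inside the peak,
and a deterministic rule is required; the choice is logged in the class
table. Third, genes missing from the expression table are `unknown` and
excluded from expressed-vs-silent tests by default (`unknown_as_silent`
flips this), since treating unmeasured genes as silent conflates absence of
evidence with repression.

## Statistics

The 2×2 chi-square is Pearson's statistic with df = 1 and no continuity
correction by default (a flag enables Yates). The orientation-abundance
test uses the table [upstream, downstream] × [expressed, silent] over peaks
inside the profile window — the same window the distance profile is drawn
from. The Wilcoxon rank-sum test is exact by enumeration when n + m ≤ 12
with no ties, and otherwise uses the normal approximation with tie and
continuity corrections; with the correction the approximation stays within
0.02 of the exact p at n = m = 6, without it the gap reaches 0.07.
Proportion intervals are Wilson score intervals (via the score test), which
behave sensibly at 0 and n successes. Raw p-values are reported; a
Benjamini–Hochberg utility exists but is off by default since the analyses
report a handful of planned tests, not a screen. Text output renders
p-values below the double-precision floor as "< 2.2e-16"; JSON keeps the
raw float.

## Motif scanning

IUPAC scanning is implemented directly because its edge semantics matter: a
sequence `N` (masked or uncalled base) matches nothing except the fully
degenerate pattern code `N`, so degenerate consensus codes never fire on
masked sequence. Matches are reported on both strands by default (peaks
have no intrinsic orientation); minus-strand hits are matches of the
reverse-complemented pattern reported by their plus-strand footprint start,
and overlapping hits are all reported. A peak "has" a motif if its summit
window contains at least one hit; multiplicity is not used in the census
fractions. The 75-nt window is the total width centered on the summit
(±37 bp); a ±75 reading is available by setting `motif_width = 151`.
Windows are clipped at chromosome ends and flagged.

The census classes are expressed and silent peaks within 1 kb of the TSS,
plus the upstream/downstream split of the expressed subset; the BRE
enrichment tests compare BRE-bearing proximal peaks against all peaks
within the 10 kb flag distance, and proximal-active against
proximal-silent.

## Co-occupancy

"Within a 150 nt window" is implemented as a maximum edge gap of 150
between intervals, inclusive — the gap semantics of standard interval
overlap machinery (`GenomicRanges::findOverlaps(maxgap=)` under the hood,
verified against an all-pairs scan in the tests). Each row percentage is
normalised by the class size, and each class peak counts once no matter how
many external peaks it touches. A summit mode (distance between 1-bp
anchors) exists behind `overlap_mode = "summit"` for fixed-width
comparisons.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, with
defaults fixed once as the package's study conditions:

- 4 chromosomes × 2 Mb of uniform ACGT sequence; 400 genes of 2–20 kb
  placed with ≥ 2 kb spacing, strands equiprobable; about half the genes
  expressed.
- 2500 peaks, 80% TSS-linked (≈ 1000 linked peaks per expression class —
  the scale at which the recovery tests are specified). A linked peak's
  summit sits at TSS + offset, strand-aware, with offsets from truncated
  normals on [−10 kb, 10 kb]: N(−300, 400) at expressed targets, N(0, 800)
  at silent ones. These reproduce the qualitative asymmetry the analysis
  tests for — an upstream bias at expressed genes, symmetric binding at
  silent ones — not any particular smoothed profile.
- Expression draws are log-normal (median 10 RPKM expressed, 0.1 silent)
  *truncated at the cutoff*, so the ledger's class labels are exact by
  construction; a `boundary_mode` puts a fifth of expressed genes at
  exactly 1.0 to exercise the inclusive boundary.
- TATA boxes are planted in 40% of expressed-target and 10% of
  silent-target summit windows; BRE in 30% of proximal and 5% of distal
  windows. Planted instances are uniform random instantiations of the
  IUPAC pattern and never overwrite one another.
- Each mark set seeds a peak from every TF peak with probability q (0.5 and
  0.2 by default), jittered within ±100 bp, over 5 background peaks/Mb.

Each artifact (sequence, genes, peaks, motifs, expression, marks) draws
from its own stream derived from the master seed, so regenerating one does
not perturb the others, and everything is bit-for-bit reproducible.

The ledger records, per peak, the linked gene and realized offset *and* the
nearest gene, distance and class labels recomputed by the generator's own
naive all-pairs scan. This matters for two reasons. First, a peak drawn
with a large offset can genuinely be nearer to a neighbouring gene's TSS;
ground truth is what the emitted data contain, not what was drawn. Second,
the generator's accounting is an independent code path from the pipeline's
indexed search, so ledger agreement is a real dual-route check.

What the generator does **not** emulate: realistic base composition or
repeats, gene clusters and overlapping genes, isoform structure,
peak-width/signal correlation, and mark-specific spatial profiles
(e.g. flanking nucleosome marks). Passing recovery tests therefore show the
pipeline's bookkeeping and estimators are correct under the generative
model, not that any biological conclusion transfers to real data.

Observed co-occupancy percentages exceed q because TSS-linked peaks
cluster: a peak can overlap a mark seeded by a *different* peak at the same
gene. The recovery tests therefore measure the collision background on
unseeded peaks and compare the overall rate against q + (1 − q) × background,
rather than against q alone; the motif-rate recovery uses the same logic
with the unplanted-window hit rate.

## Numerical and degenerate-input choices

Histogram bins are half-open `[lo, lo + bin)` with the single closure
exception that a distance exactly at `+window` joins the last bin, so
in-window counts are conserved. Empty classes yield `NaN` fractions flagged
with `n_peaks = 0` rather than errors; empty external sets give 0% columns;
an empty class in `overlap_fraction` returns an undefined flag, not a
crash. Chi-square tables with a zero marginal raise an error advising an
exact test. Even motif widths place the extra base downstream of the
summit. The narrowPeak summit sentinel −1 maps to an absent summit, which
falls back to the midpoint anchor.

## Problem sizes

The test suite and the acceptance script run the full generator at its
default scale (8 Mb genome, 2500 peaks) once, the oracle-equivalence suites
at 1000+ random instances per operation, the null calibration at 10 000
Wilcoxon replicates, and the power check over 100 generator seeds
(annotation-only, skipping sequence synthesis); the whole suite completes
in a few minutes on one core. These sizes were chosen to keep Monte-Carlo
standard errors well inside the asserted tolerances.

## Known limitations

Single nearest-gene assignment only (no multi-gene windows); no
exon/intron sub-classification; no signal-level (bigWig) co-occupancy; no
PWM scoring — consensus scanning is deliberately the same primitive the
motivating analysis used; GTF input uses `gene` records only. The expression
unit is gene-level RPKM; isoform-level quantification is out of scope.
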