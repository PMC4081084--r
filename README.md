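# peakscape

Downstream analysis of transcription-factor ChIP-seq peak calls, built
around the questions one asks after peak calling: where does a factor bind
relative to genes, does binding track target-gene expression, which
core-promoter elements sit under the peak summits, and which other factors
or chromatin marks co-occupy the same sites.

The motivating use case is a genome-wide binding study of the transcription
factor TFII-I in the human K562 erythroleukemia line, where peaks were
assigned to nearest genes, stratified by target-gene expression at an RPKM
cutoff of 1, profiled in a ±2 kb TSS window, censused for core-promoter
elements in 75-nt summit windows, and correlated with ENCODE occupancy
tracks within a 150 nt gap tolerance. All of those operations are generic;
`peakscape` implements them for any peak set, gene annotation and
expression table.

## What it computes

For a peak set *P*, gene models *G* (strand-aware TSS/TES) and an
expression table:

- **Nearest-gene annotation.** Each peak's reference point (summit, else
  interval midpoint) is assigned to the gene minimizing the absolute signed
  TSS distance *d* (*d* = point − TSS on `+` genes, TSS − point on `-`
  genes, so negative is always upstream). Peaks are classified as
  TSS / TES / intragenic / upstream / downstream, and as proximal
  (|*d*| ≤ 1 kb, inclusive) or distal.
- **Expression stratification.** Genes with RPKM ≥ 1 are expressed
  (`compute_rpkm` gives reads × 10⁹ / (length × library size)); peaks
  inherit their target gene's class; bookkeeping yields the six analysis
  classes (expressed, silent, proximal, distal, proximal-upstream,
  proximal-downstream) plus unique-target-gene counts and shares.
- **Distribution statistics.** Binned TSS-distance profiles per class; a
  Pearson 2×2 chi-square on upstream/downstream abundance by expression
  class; Wilcoxon rank-sum tests (exact by enumeration for n+m ≤ 12
  untied, normal approximation otherwise) on |*d*| for expressed vs silent
  targets; Wilson score intervals for proportions.
- **Motif census.** IUPAC consensus scanning (both strands, overlapping
  hits, sequence `N` matches only pattern code `N`) of the five
  core-promoter elements — TATAAA, INR `YYANWYY`, DPE `RGWYV`, BRE
  `SSRCGCC`, and the TFII-I/BEN site `RGATTR` — in 75-nt summit windows of
  peaks within 1 kb of a TSS, plus chi-square tests for BRE enrichment in
  proximal peaks and at active genes.
- **Co-occupancy.** The percentage of peaks in each class lying within a
  150 nt edge gap of any peak in each external set (row-normalised by class
  size), with an alternative summit-distance mode.
- **Synthetic data.** `simulate_dataset()` generates a genome, gene models,
  expression, TF peaks with class-dependent TSS-offset models (expressed
  targets biased upstream), planted motif instances and co-occupying mark
  sets, together with a ground-truth ledger, so every stage of the pipeline
  is testable without any external download.

## Worked example

```r
library(peakscape)
ds <- simulate_dataset(sim_config(seed = 20140915), dir = "results/simdata")
rep <- run_analysis(pipeline_config(
  peaks = ds$peaks, genes = ds$genes, expression = ds$expression,
  genome = ds$genome, marks = ds$marks))
unlist(rep$stratification$class_counts)
#>               total           expressed              silent             unknown
#>                2500                1284                1216                   0
#>            proximal              distal   proximal_upstream proximal_downstream
#>                1835                 665                1214                 621
rep$stats$downstream_abundance$p_value
#> [1] 1.021278e-39
```

The class counts match the generator's ground-truth ledger exactly; the
chi-square p-value reflects the planted asymmetry (expressed-target peaks
biased ~300 bp upstream of the TSS, silent-target peaks symmetric). The
numbered scripts under `analysis/` run the same stages from the files on
disk and print each stage's findings (location distribution, class table,
motif census, overlap matrix).

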