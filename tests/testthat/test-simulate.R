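# Synthetic-data generator: determinism, degenerate settings, statistical
# calibration, ground-truth ledger consistency, file round-trips.

fast_cfg <- function(seed = 1, n_genes = 40L, n_peaks = 200L, ...) {
  sim_config(seed = seed, n_chrom = 2L, chrom_length = 3e5,
             n_genes = n_genes, gene_length = c(2000L, 8000L),
             n_peaks = n_peaks, ...)
}

test_that("the generator is reproducible bit for bit under a fixed seed", {
  d1 <- simulate_dataset(fast_cfg(5))
  d2 <- simulate_dataset(fast_cfg(5))
  expect_identical(d1$genome, d2$genome)
  expect_identical(d1$peaks, d2$peaks)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$ledger, d2$ledger)
  d3 <- simulate_dataset(fast_cfg(6))
  expect_false(identical(d1$peaks, d3$peaks))
})

test_that("degenerate sizes are handled", {
  g0 <- simulate_genes(fast_cfg(1, n_genes = 0L))
  expect_equal(nrow(g0$genes), 0L)
  p0 <- simulate_peaks(fast_cfg(1, n_peaks = 0L), g0$genes, g0$gene_truth)
  expect_equal(nrow(p0$peaks), 0L)
  expect_error(simulate_genes(sim_config(n_chrom = 1L, chrom_length = 1e4,
                                         n_genes = 50L)),
               "infeasible packing")
})

test_that("sequence base composition is uniform within binomial error", {
  cfg <- sim_config(seed = 2, n_chrom = 1L, chrom_length = 2e5, n_genes = 0L)
  s <- simulate_sequence(cfg)[[1]]
  counts <- table(strsplit(s, "")[[1]])
  n <- nchar(s)
  se <- sqrt(0.25 * 0.75 / n)
  for (b in c("A", "C", "G", "T"))
    expect_lt(abs(counts[[b]] / n - 0.25), 3 * se + 1e-3)
})

test_that("genes respect spacing, bounds, and expression truth margins", {
  cfg <- fast_cfg(3)
  gg <- simulate_genes(cfg)
  g <- gg$genes
  for (ch in unique(g$chrom)) {
    sub <- g[g$chrom == ch, ]
    sub <- sub[order(sub$span_start), ]
    expect_true(all(sub$span_start >= 0 & sub$span_end <= cfg$chrom_length))
    if (nrow(sub) > 1)
      expect_true(all(sub$span_start[-1] - sub$span_end[-nrow(sub)] >=
                        cfg$gene_spacing))
  }
  expr <- simulate_expression(cfg, gg$gene_truth)
  lab <- label_expressed(expr, cfg$rpkm_cutoff)
  expect_equal(unname(lab[gg$gene_truth$gene_id]), gg$gene_truth$class)
})

test_that("boundary mode places expressed genes exactly at the cutoff", {
  cfg <- fast_cfg(4, boundary_mode = TRUE)
  gg <- simulate_genes(cfg)
  expr <- simulate_expression(cfg, gg$gene_truth)
  at <- expr$rpkm == cfg$rpkm_cutoff
  expect_gt(sum(at), 0)
  expect_equal(unname(label_expressed(expr)[expr$gene_id[at]]),
               rep("expressed", sum(at)))
})

test_that("a near-degenerate offset model places summits where configured", {
  cfg <- fast_cfg(5, frac_tss_linked = 1,
                  offset_expressed = c(mean = -300, sd = 1),
                  offset_silent = c(mean = -300, sd = 1))
  gg <- simulate_genes(cfg)
  pk <- simulate_peaks(cfg, gg$genes, gg$gene_truth)
  led <- pk$ledger
  expect_true(all(led$linked))
  expect_true(all(abs(led$drawn_offset + 300) <= 5))
  # strand-aware: recompute from emitted coordinates
  gi <- match(led$linked_gene, gg$genes$gene_id)
  d <- signed_tss_distance(reference_point(pk$peaks),
                           gg$genes$tss[gi], gg$genes$strand[gi])
  expect_equal(d, led$drawn_offset)
})

test_that("the ledger is self-consistent with the emitted peaks", {
  cfg <- fast_cfg(6)
  gg <- simulate_genes(cfg)
  pk <- simulate_peaks(cfg, gg$genes, gg$gene_truth)
  expect_equal(reference_point(pk$peaks), pk$ledger$summit)
  # orientation recorded only for |distance| <= 1 kb, sign rule as documented
  led <- pk$ledger
  prox <- !is.na(led$true_distance) & abs(led$true_distance) <= 1000
  expect_true(all(is.na(led$orientation[!prox])))
  expect_equal(led$orientation[prox],
               ifelse(led$true_distance[prox] < 0, "upstream", "downstream"))
})

test_that("motif planting rates 0 and 1 behave as limits", {
  cfg0 <- fast_cfg(7, plant_rates = data.frame(pattern = "TATAAA",
                                               class = "expressed",
                                               rate = 0))
  gg <- simulate_genes(cfg0)
  pk <- simulate_peaks(cfg0, gg$genes, gg$gene_truth)
  genome <- simulate_sequence(cfg0)
  pm0 <- plant_motifs(genome, pk$peaks, pk$ledger, cfg0)
  expect_identical(pm0$genome, genome)
  expect_equal(nrow(pm0$planted), 0L)

  cfg1 <- fast_cfg(7, plant_rates = data.frame(pattern = "TATAAA",
                                               class = "expressed",
                                               rate = 1))
  pm1 <- plant_motifs(genome, pk$peaks, pk$ledger, cfg1)
  expressed <- pk$ledger$expr_class == "expressed"
  hit <- peak_has_motif(pk$peaks, pm1$genome, "TATAAA")
  # every expressed-class window contains a planted instance unless skipped
  expect_gte(sum(hit[expressed]) + pm1$n_skipped, sum(expressed))
})

test_that("planted instances land inside their peak's summit window", {
  cfg <- fast_cfg(8)
  ds <- simulate_dataset(cfg)
  pl <- ds$ledger$planted
  expect_gt(nrow(pl), 0)
  win <- summit_region(ds$peaks, 75L)
  w <- win[match(pl$peak_id, win$peak_id), ]
  expect_true(all(pl$pos >= w$start))
  expect_true(all(pl$pos + nchar(pl$instance) <= w$end))
  # instances really are in the genome and match their pattern
  for (j in sample(nrow(pl), min(20, nrow(pl)))) {
    s <- substring(ds$genome[[pl$chrom[j]]], pl$pos[j] + 1,
                   pl$pos[j] + nchar(pl$instance[j]))
    expect_equal(s, pl$instance[j])
    expect_equal(oracle_scan(s, pl$pattern[j], "plus")$position, 0L)
  }
})

test_that("mark co-occupancy limits q=0 and q=1 are exact without background", {
  cfg1 <- fast_cfg(9, marks = list(m = list(q = 1, background_per_mb = 0)))
  ds1 <- simulate_dataset(cfg1, sequence = FALSE)
  f1 <- overlap_fraction(ds1$peaks, ds1$marks$m, 150L)
  expect_equal(f1$percent, 100)
  cfg0 <- fast_cfg(9, marks = list(m = list(q = 0, background_per_mb = 0)))
  ds0 <- simulate_dataset(cfg0, sequence = FALSE)
  expect_equal(nrow(ds0$marks$m), 0L)
  expect_equal(overlap_fraction(ds0$peaks, ds0$marks$m, 150L)$percent, 0)
})

test_that("written files re-read through the package reproduce the objects", {
  dir <- tempfile()
  ds <- simulate_dataset(fast_cfg(10), dir = dir)
  expect_equal(read_genome(file.path(dir, "genome.fa")), ds$genome)
  expect_equal(read_gene_models(file.path(dir, "genes.tsv")), ds$genes)
  expr <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(expr$gene_id, ds$expression$gene_id)
  expect_equal(expr$rpkm, ds$expression$rpkm, tolerance = 1e-12)
  pk <- read_peaks(file.path(dir, "tf_peaks.narrowPeak"), "narrowPeak")
  expect_equal(pk$start, ds$peaks$start)
  expect_equal(pk$summit_offset, ds$peaks$summit_offset)
  mk <- read_peaks(file.path(dir, "mark_mark_A.narrowPeak"), "narrowPeak")
  expect_equal(mk$start, ds$marks$mark_A$start)
})
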