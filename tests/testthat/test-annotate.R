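# Nearest-gene assignment, signed distances, location and proximity classes,
# TSS-window histograms.

test_that("reference point prefers the summit, else the floored midpoint", {
  p <- make_peaks("chr1", c(100L, 100L, 100L), c(200L, 200L, 201L),
                  c(50L, NA, NA))
  expect_equal(reference_point(p), c(150L, 150L, 150L))
})

test_that("signed TSS distance is strand-aware with upstream negative", {
  expect_equal(signed_tss_distance(900L, 1000L, "+"), -100L)
  # minus-strand gene spanning [100,200): TSS at 199, higher coords upstream
  expect_equal(signed_tss_distance(250L, 199L, "-"), -51L)
  expect_equal(signed_tss_distance(1000L, 1000L, "+"), 0L)
  expect_error(signed_tss_distance(5L, 10L, "+", "chr1", "chr2"),
               "different chromosomes")
})

test_that("strand flip with mirrored TSS negates the signed distance", {
  set.seed(5)
  for (i in 1:50) {
    s <- sample.int(1e5, 1); e <- s + sample.int(2e4, 1)
    pt <- sample.int(1.5e5, 1)
    gp <- gene_models("g", "chr1", s, e, "+")
    gm <- gene_models("g", "chr1", s, e, "-")
    dp <- signed_tss_distance(pt, gp$tss, "+")
    # mirror the point about the span centre so it sits at the mirrored tss
    pt_m <- s + e - 1L - pt
    dm <- signed_tss_distance(pt_m, gm$tss, "-")
    expect_equal(dm, dp)
  }
})

test_that("nearest-gene choice minimises |TSS distance| with deterministic ties", {
  genes <- gene_models(c("gA", "gB"), "chr1", c(1000L, 2000L),
                       c(1900L, 2900L), c("+", "+"))
  p <- make_peaks("chr1", 1300L, 1500L)  # midpoint 1400
  a <- assign_nearest_gene(p, genes)
  expect_equal(a$gene_id, "gA")
  expect_equal(a$signed_distance, 400L)

  # exact tie at 500 bp from both TSSs -> lexicographically smallest id
  tie <- gene_models(c("gZ", "gB2"), "chr1", c(1000L, 2000L),
                     c(1900L, 2900L), c("+", "+"))
  p2 <- make_peaks("chr1", 1400L, 1600L)  # midpoint 1500
  expect_equal(assign_nearest_gene(p2, tie)$gene_id, "gB2")

  # chromosome with no genes
  p3 <- make_peaks("chrX", 100L, 200L)
  a3 <- assign_nearest_gene(p3, genes)
  expect_equal(a3$gene_id, "unassigned")
  expect_true(is.na(a3$signed_distance))
})

test_that("assignment equals the exhaustive all-pairs oracle", {
  set.seed(42)
  genes <- random_genes(100)
  peaks <- random_peaks(100)
  got <- assign_nearest_gene(peaks, genes)
  want <- oracle_nearest(peaks, genes)
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$signed_distance, want$signed_distance)
})

test_that("assignment is invariant to gene input order", {
  set.seed(43)
  genes <- random_genes(60)
  peaks <- random_peaks(60)
  a <- assign_nearest_gene(peaks, genes)
  b <- assign_nearest_gene(peaks, genes[sample(nrow(genes)), ])
  expect_equal(a$gene_id, b$gene_id)
  expect_equal(a$signed_distance, b$signed_distance)
})

test_that("genic-location categories follow the stated precedence", {
  g <- gene_models("g1", "chr1", 1000L, 2000L, "+")  # tss 1000, tes 1999
  expect_equal(classify_genic_location(make_peaks("chr1", 950L, 1050L), g),
               "TSS")
  expect_equal(classify_genic_location(make_peaks("chr1", 1950L, 2050L), g),
               "TES")
  expect_equal(classify_genic_location(make_peaks("chr1", 1200L, 1300L), g),
               "intragenic")
  expect_equal(classify_genic_location(make_peaks("chr1", 300L, 400L), g),
               "upstream")
  expect_equal(classify_genic_location(make_peaks("chr1", 2100L, 2200L), g),
               "downstream")
  # minus-strand gene: higher coordinates are upstream
  gm <- gene_models("g2", "chr1", 100L, 200L, "-")  # tss 199
  expect_equal(classify_genic_location(make_peaks("chr1", 300L, 400L), gm),
               "upstream")
  # peak covering both TSS and TES of a short gene -> TSS wins
  short <- gene_models("g3", "chr1", 1000L, 1100L, "+")
  expect_equal(classify_genic_location(make_peaks("chr1", 950L, 1150L),
                                       short), "TSS")
})

test_that("every assigned peak gets exactly one location and one proximity", {
  set.seed(44)
  genes <- random_genes(80)
  peaks <- random_peaks(200)
  a <- assign_nearest_gene(peaks, genes)
  ok <- a$gene_id != "unassigned"
  expect_true(all(a$location[ok] %in%
                    c("TSS", "TES", "intragenic", "upstream", "downstream")))
  expect_true(all(a$proximity[ok] %in% c("proximal", "distal")))
  loc_sum <- sum(table(a$location[ok]))
  expect_equal(loc_sum, sum(ok))
})

test_that("proximity boundary is inclusive", {
  expect_equal(proximity_class(c(-1000L, 1000L, 1001L, 0L), 1000L),
               c("proximal", "proximal", "distal", "proximal"))
  expect_error(proximity_class(0L, 0L))
})

test_that("TSS-window histogram equals a direct per-distance tally", {
  set.seed(45)
  d <- sample(-2500:2500, 1000, replace = TRUE)
  cls <- sample(c("expressed", "silent"), 1000, replace = TRUE)
  prof <- tss_window_profile(d, cls, window = 2000L, bin = 100L)
  for (cl in c("expressed", "silent")) {
    sel <- cls == cl & abs(d) <= 2000
    tally <- integer(40)
    for (x in d[sel]) {
      b <- min((x + 2000L) %/% 100L + 1L, 40L)
      tally[b] <- tally[b] + 1L
    }
    expect_equal(prof[[paste0("count_", cl)]], tally)
    expect_equal(sum(prof[[paste0("count_", cl)]]), sum(sel))
    expect_equal(sum(prof[[paste0("density_", cl)]]), 1)
  }
})

test_that("histogram handles degenerate inputs", {
  p0 <- tss_window_profile(rep(0L, 5), rep("expressed", 5))
  expect_equal(sum(p0$count_expressed), 5L)
  expect_equal(p0$count_expressed[p0$bin_lo == 0], 5L)
  pe <- tss_window_profile(integer(0), character(0))
  expect_equal(nrow(pe), 40L)
  expect_error(tss_window_profile(0L, "a", window = 2000L, bin = 300L),
               "divide")
})
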