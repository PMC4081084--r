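# IUPAC scanning, summit windows, motif census, BRE enrichment bookkeeping.

test_that("reverse complement behaves on the ACGTN alphabet", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AAAC"), "GTTT")
  expect_equal(revcomp("ANT"), "ANT")
  expect_error(revcomp("ACGU"), "invalid")
  set.seed(7)
  for (i in 1:20) {
    s <- random_dna(50, c("A", "C", "G", "T", "N"))
    expect_equal(revcomp(revcomp(s)), s)
  }
})

test_that("IUPAC scanning finds literal and degenerate matches", {
  expect_equal(scan_iupac("GGTATAAAGG", "TATAAA", strands = "plus"),
               data.frame(position = 2L, strand = "+"),
               ignore_attr = TRUE)
  # YYANWYY matched at position 0 of CCATTCC
  hit <- scan_iupac("CCATTCC", "YYANWYY", strands = "plus")
  expect_equal(hit$position, 0L)
  expect_equal(nrow(scan_iupac("GGGGGG", "TATAAA")), 0L)
  expect_error(scan_iupac("ACGT", "TAX"), "invalid IUPAC")
})

test_that("sequence N matches only the fully degenerate pattern code", {
  expect_equal(nrow(scan_iupac("TANAAA", "TATAAA", strands = "plus")), 0L)
  expect_equal(nrow(scan_iupac("TANAAA", "TAWAAA", strands = "plus")), 0L)
  expect_equal(scan_iupac("TANAAA", "TANAAA", strands = "plus")$position, 0L)
})

test_that("minus-strand hits are reported by plus-strand footprint", {
  # GTTT at position 4 is AAAC on the minus strand
  hit <- scan_iupac("CCCCGTTT", "AAAC")
  expect_equal(hit$position, 4L)
  expect_equal(hit$strand, "-")
})

test_that("plus-strand scan of a non-degenerate pattern equals substring search", {
  set.seed(8)
  for (i in 1:20) {
    s <- random_dna(300)
    pat <- random_dna(5)
    got <- scan_iupac(s, pat, strands = "plus")$position
    want <- as.integer(gregexpr(paste0("(?=", pat, ")"), s,
                                perl = TRUE)[[1]]) - 1L
    want <- want[want >= 0]
    expect_equal(got, want)
  }
})

test_that("scanning agrees with the brute-force set-expansion oracle", {
  set.seed(9)
  pats <- core_promoter_patterns()$pattern
  for (i in 1:40) {
    s <- random_dna(200, c("A", "C", "G", "T", if (i %% 4 == 0) "N"))
    for (pat in pats) {
      got <- scan_iupac(s, pat)
      want <- oracle_scan(s, pat)
      expect_equal(got$position, want$position)
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("scanning agrees with Biostrings on N-free sequence", {
  set.seed(10)
  for (pat in c("TATAAA", "SSRCGCC", "YYANWYY")) {
    s <- random_dna(500)
    got <- scan_iupac(s, pat, strands = "plus")$position
    bs <- Biostrings::matchPattern(pat, Biostrings::DNAString(s),
                                   fixed = "subject")
    expect_equal(got, BiocGenerics::start(bs) - 1L)
  }
})

test_that("both-strand scan of an rc-palindromic pattern pairs its hits", {
  set.seed(11)
  s <- paste0(random_dna(40), "ACGCGT", random_dna(40))  # rc(ACGCGT)=ACGCGT
  hit <- scan_iupac(s, "ACGCGT")
  expect_equal(sum(hit$strand == "+"), sum(hit$strand == "-"))
  expect_equal(hit$position[hit$strand == "+"],
               hit$position[hit$strand == "-"])
})

test_that("summit windows are centered, clipped, and validated", {
  p <- make_peaks("chr1", 900L, 1101L, 100L)  # summit at 1000
  w <- summit_region(p, 75L)
  expect_equal(w$start, 963L)
  expect_equal(w$end, 1038L)
  expect_equal(w$end - w$start, 75L)
  w1 <- summit_region(p, 1L)
  expect_equal(c(w1$start, w1$end), c(1000L, 1001L))
  # near the chromosome start the window is clipped and flagged
  pc <- make_peaks("chr1", 0L, 40L, 10L)
  wc <- summit_region(pc, 75L, chrom_lengths = c(chr1 = 5000L))
  expect_equal(wc$start, 0L)
  expect_true(wc$clipped)
  expect_lt(wc$end - wc$start, 75L)
  expect_error(summit_region(make_peaks("chr1", 6000L, 6100L), 75L,
                             chrom_lengths = c(chr1 = 5000L)),
               "outside chromosome")
  expect_error(summit_region(p, 75L, chrom_lengths = c(chr2 = 5000L)),
               "absent")
})

test_that("census counts at-least-one matches per class and pattern", {
  genome <- c(chr1 = paste0(strrep("C", 100), "TATAAA", strrep("C", 100)))
  peaks <- make_peaks("chr1", c(80L, 150L), c(130L, 200L), c(23L, 25L),
                      id = c("hit", "miss"))
  cls <- list(with = "hit", without = "miss", both = c("hit", "miss"),
              none = character(0))
  cen <- motif_census(peaks, genome, cls,
                      patterns = data.frame(name = "TATA",
                                            pattern = "TATAAA"))
  frac <- setNames(cen$fraction, cen$class)
  expect_equal(frac[["with"]], 1)
  expect_equal(frac[["without"]], 0)
  expect_equal(frac[["both"]], 0.5)
  expect_true(is.nan(frac[["none"]]))
  expect_equal(cen$n_peaks[cen$class == "none"], 0L)
  # the universal pattern N matches every non-empty class
  cenN <- motif_census(peaks, genome, cls["both"],
                       patterns = data.frame(name = "any", pattern = "N"))
  expect_equal(cenN$fraction, 1)
})

test_that("census fractions are invariant to peak input order", {
  set.seed(12)
  genome <- c(chr1 = random_dna(50000))
  peaks <- random_peaks(100, "chr1", len = 49000)
  cls <- list(a = peaks$peak_id[1:50], b = peaks$peak_id[51:100])
  c1 <- motif_census(peaks, genome, cls)
  c2 <- motif_census(peaks[sample(nrow(peaks)), ], genome, cls)
  expect_equal(c1, c2)
})

test_that("background TATA hit rate on random windows matches the analytic rate", {
  set.seed(13)
  n <- 4000
  width <- 75L
  hits <- vapply(seq_len(n), function(i)
    nrow(scan_iupac(random_dna(width), "TATAAA")) > 0, logical(1))
  phat <- mean(hits)
  # per-position, per-strand match probability 4^-6 over 70 start positions;
  # both strands, small overlap correction ignored
  p0 <- 1 - (1 - 4^-6)^(2 * (width - 6 + 1))
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(phat - p0), 3 * se + 0.002)
})

test_that("BRE enrichment tables are assembled correctly from counts", {
  # equal BRE rates -> no association
  r0 <- bre_enrichment(20, 100, 60, 300, 10, 50, 10, 50)
  expect_lt(r0$proximal_vs_all$statistic, 1e-10)
  expect_equal(r0$proximal_vs_all$p_value, 1)
  expect_equal(r0$active_vs_silent$p_value, 1)
  # hand-assembled tables
  r <- bre_enrichment(30, 100, 50, 400, 25, 60, 5, 40)
  expect_equal(unname(r$proximal_vs_all$table),
               matrix(c(30, 70, 20, 280), 2))
  expect_equal(unname(r$active_vs_silent$table),
               matrix(c(25, 35, 5, 35), 2))
  expect_equal(r$proximal_vs_all$statistic,
               oracle_pearson(matrix(c(30, 70, 20, 280), 2)),
               tolerance = 1e-10)
})
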