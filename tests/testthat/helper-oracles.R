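# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive and share no code with the package internals.

make_peaks <- function(chrom, start, end, summit_offset = NA_integer_,
                       id = NULL) {
  n <- length(start)
  if (is.null(id)) id <- sprintf("p%03d", seq_len(n))
  data.frame(peak_id = id, chrom = rep_len(chrom, n),
             start = as.integer(start), end = as.integer(end),
             summit_offset = as.integer(rep_len(summit_offset, n)),
             score = NA_real_, stringsAsFactors = FALSE)
}

random_peaks <- function(n, chroms = c("chr1", "chr2", "chr3"),
                         len = 1e6, width = c(100, 500)) {
  w <- sample(width[1]:width[2], n, replace = TRUE)
  start <- sample.int(len - max(width) - 1L, n, replace = TRUE)
  has_summit <- runif(n) < 0.7
  so <- ifelse(has_summit, vapply(w, function(x) sample.int(x, 1L) - 1L,
                                  integer(1)), NA_integer_)
  make_peaks(sample(chroms, n, replace = TRUE), start, start + w, so)
}

random_genes <- function(n, chroms = c("chr1", "chr2", "chr3"), len = 1e6) {
  start <- sample.int(len - 30000L, n, replace = TRUE)
  gl <- sample(1000:20000, n, replace = TRUE)
  gene_models(sprintf("g%03d", sample(seq_len(10 * n), n)),
              sample(chroms, n, replace = TRUE),
              start, start + gl, sample(c("+", "-"), n, replace = TRUE))
}

# Exhaustive scan over every gene-peak pair: minimal |TSS distance| from the
# peak's summit (else midpoint), ties by smallest gene_id.
oracle_nearest <- function(peaks, genes) {
  out <- data.frame(peak_id = peaks$peak_id,
                    gene_id = rep("unassigned", nrow(peaks)),
                    signed_distance = rep(NA_integer_, nrow(peaks)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    pt <- if (is.na(peaks$summit_offset[i]))
      (peaks$start[i] + peaks$end[i]) %/% 2 else
        peaks$start[i] + peaks$summit_offset[i]
    best <- NULL
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != peaks$chrom[i]) next
      d <- if (genes$strand[j] == "+") pt - genes$tss[j] else genes$tss[j] - pt
      if (is.null(best) || abs(d) < abs(best$d) ||
          (abs(d) == abs(best$d) && genes$gene_id[j] < best$id))
        best <- list(id = genes$gene_id[j], d = d)
    }
    if (!is.null(best)) {
      out$gene_id[i] <- best$id
      out$signed_distance[i] <- best$d
    }
  }
  out
}

# Naive IUPAC scan: expand the pattern into per-position base sets and slide.
oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N"))

oracle_scan_one_strand <- function(seq, pattern) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  k <- length(pc); L <- length(sc)
  hits <- integer(0)
  if (L >= k) for (i in 1:(L - k + 1)) {
    ok <- TRUE
    for (j in 1:k) if (!sc[i + j - 1] %in% oracle_iupac_sets[[pc[j]]]) {
      ok <- FALSE; break
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

oracle_revcomp_pattern <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(pattern, "")[[1]]]), collapse = "")
}

oracle_scan <- function(seq, pattern, strands = "both") {
  plus <- oracle_scan_one_strand(seq, pattern)
  res <- data.frame(position = plus, strand = rep("+", length(plus)),
                    stringsAsFactors = FALSE)
  if (strands == "both") {
    minus <- oracle_scan_one_strand(seq, oracle_revcomp_pattern(pattern))
    res <- rbind(res, data.frame(position = minus,
                                 strand = rep("-", length(minus)),
                                 stringsAsFactors = FALSE))
  }
  res[order(res$position, res$strand), , drop = FALSE]
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# All-pairs overlap scan with the edge-gap definition.
oracle_overlap_fraction <- function(classA, setB, maxgap) {
  hit <- logical(nrow(classA))
  for (i in seq_len(nrow(classA))) {
    for (j in seq_len(nrow(setB))) {
      if (classA$chrom[i] != setB$chrom[j]) next
      gap <- max(setB$start[j] - classA$end[i],
                 classA$start[i] - setB$end[j], 0)
      if (gap <= maxgap) { hit[i] <- TRUE; break }
    }
  }
  100 * sum(hit) / nrow(classA)
}

# Textbook Pearson statistic for a 2x2 table.
oracle_pearson <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Closed-form Wilson score interval.
oracle_wilson <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(ctr - hw, ctr + hw)
}
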