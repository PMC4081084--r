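# IUPAC consensus scanning in summit-centered windows and the targeted
# core-promoter element census, including the BRE enrichment tests.

# Pattern codes map to allowed sequence characters. Sequence N is ambiguous
# base-call filler: it matches nothing except the fully degenerate pattern
# code N, so degenerate codes never fire on masked sequence.
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N"))

.iupac_complement <- c(A = "T", C = "G", G = "C", T = "A",
                       R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                       B = "V", D = "H", H = "D", V = "B", N = "N")

.check_iupac <- function(pattern) {
  if (nchar(pattern) == 0) stop("empty IUPAC pattern")
  chars <- strsplit(pattern, "")[[1]]
  bad <- !chars %in% names(.iupac_sets)
  if (any(bad))
    stop("invalid IUPAC code in pattern: ", paste(chars[bad], collapse = ""))
  chars
}

#' Reverse complement of a DNA string
#'
#' Alphabet `A,C,G,T,N`; `N` maps to `N`.
#'
#' @param seq DNA string.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  if (grepl("[^ACGTN]", seq)) stop("invalid character in DNA string")
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Reverse complement of an IUPAC pattern (degenerate codes complemented).
revcomp_iupac <- function(pattern) {
  chars <- .check_iupac(pattern)
  paste(rev(unname(.iupac_complement[chars])), collapse = "")
}

.scan_plus <- function(chars, pat_chars) {
  k <- length(pat_chars)
  npos <- length(chars) - k + 1L
  if (npos < 1L) return(integer(0))
  ok <- rep(TRUE, npos)
  for (i in seq_len(k))
    ok <- ok & chars[i:(i + npos - 1L)] %in% .iupac_sets[[pat_chars[i]]]
  which(ok)
}

#' Scan a sequence for an IUPAC consensus pattern
#'
#' A plus-strand match requires every sequence base to fall in the pattern
#' position's allowed set. Minus-strand hits are matches of the
#' reverse-complemented pattern, reported by the 0-based plus-strand start of
#' their footprint. Overlapping matches are all reported.
#'
#' @param seq DNA string over `A,C,G,T,N`.
#' @param pattern IUPAC consensus string.
#' @param strands `"both"` (default) or `"plus"`.
#' @return `data.frame` with `position` (0-based plus-strand footprint start)
#'   and `strand` (`"+"`/`"-"`), ordered by position; zero rows when nothing
#'   matches.
#' @examples
#' scan_iupac("GGTATAAAGG", "TATAAA", strands = "plus")$position  # 2
#' @export
scan_iupac <- function(seq, pattern, strands = c("both", "plus")) {
  strands <- match.arg(strands)
  pat_chars <- .check_iupac(pattern)
  chars <- strsplit(seq, "")[[1]]
  pos <- .scan_plus(chars, pat_chars)
  hits <- data.frame(position = pos - 1L,
                     strand = rep("+", length(pos)),
                     stringsAsFactors = FALSE)
  if (strands == "both") {
    rc <- strsplit(revcomp_iupac(pattern), "")[[1]]
    pos_m <- .scan_plus(chars, rc)
    hits <- rbind(hits, data.frame(position = pos_m - 1L,
                                   strand = rep("-", length(pos_m)),
                                   stringsAsFactors = FALSE))
  }
  hits[order(hits$position, hits$strand), , drop = FALSE]
}

#' Summit-centered sequence window of a peak
#'
#' The interval `[point - (width-1)/2, point + (width+1)/2)` of length
#' exactly `width` around each peak's reference point (summit, else
#' midpoint), clipped to chromosome bounds; clipped windows are flagged.
#'
#' @param peaks peak `data.frame`.
#' @param width window width in nt, default 75 (odd widths center exactly;
#'   even widths put the extra base downstream).
#' @param chrom_lengths named integer vector of chromosome lengths used for
#'   clipping; reference points outside their chromosome are an error.
#' @return `data.frame` with `peak_id`, `chrom`, `start`, `end`, `clipped`.
#' @export
summit_region <- function(peaks, width = 75L, chrom_lengths = NULL) {
  stopifnot(width >= 1)
  point <- reference_point(peaks)
  lo <- point - (width - 1L) %/% 2L
  hi <- lo + width
  clipped <- rep(FALSE, length(lo))
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[peaks$chrom])
    if (any(is.na(len)))
      stop("chromosome absent from genome: peak ",
           peaks$peak_id[which(is.na(len))[1]])
    if (any(point < 0 | point >= len))
      stop("reference point outside chromosome: peak ",
           peaks$peak_id[which(point < 0 | point >= len)[1]])
    clipped <- lo < 0L | hi > len
    hi <- pmin(hi, len)
  }
  lo <- pmax(lo, 0L)
  data.frame(peak_id = peaks$peak_id, chrom = peaks$chrom,
             start = as.integer(lo), end = as.integer(hi),
             clipped = clipped, stringsAsFactors = FALSE)
}

# Extract the summit-window sequences for a peak table.
window_sequences <- function(peaks, genome, width = 75L) {
  lens <- vapply(genome, nchar, integer(1))
  win <- summit_region(peaks, width, chrom_lengths = lens)
  substring(genome[win$chrom], win$start + 1L, win$end)
}

#' Which peaks carry at least one match of a pattern in their summit window
#'
#' @param peaks peak `data.frame`.
#' @param genome named character vector of chromosome sequences.
#' @param pattern IUPAC consensus string.
#' @param width summit-window width in nt (default 75).
#' @param strands `"both"` (default) or `"plus"`.
#' @return Logical vector, one element per peak.
#' @export
peak_has_motif <- function(peaks, genome, pattern, width = 75L,
                           strands = "both") {
  seqs <- window_sequences(peaks, genome, width)
  pat <- .check_iupac(pattern)
  rc <- strsplit(revcomp_iupac(pattern), "")[[1]]
  vapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    length(.scan_plus(chars, pat)) > 0 ||
      (strands == "both" && length(.scan_plus(chars, rc)) > 0)
  }, logical(1), USE.NAMES = FALSE)
}

#' The five core-promoter consensus elements scanned by the census
#'
#' Loaded from the plain-text registry shipped with the package: the TATA box
#' (TATAAA), the initiator INR (YYANWYY), the downstream promoter element DPE
#' (RGWYV), the TFII-B recognition element BRE (SSRCGCC), and the TFII-I/BEN
#' SELEX consensus (RGATTR).
#'
#' @return `data.frame` with columns `name`, `pattern`.
#' @export
core_promoter_patterns <- function() {
  path <- system.file("extdata", "core_promoter_elements.tsv",
                      package = "peakscape")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Core-promoter motif census over peak classes
#'
#' For each peak class and each IUPAC pattern, the fraction of peaks whose
#' summit window contains at least one match (either strand by default).
#' Match multiplicity does not matter for the fraction.
#'
#' @param peaks peak `data.frame`.
#' @param genome named character vector of chromosome sequences.
#' @param classes named list; each element is a character vector of peak ids
#'   defining one class (classes may overlap).
#' @param patterns `data.frame` with `name` and `pattern` columns
#'   (default [core_promoter_patterns()]).
#' @param width summit-window width in nt, default 75.
#' @param strands `"both"` (default) or `"plus"`.
#' @return `data.frame` with `class`, `pattern`, `n_peaks`, `n_with_match`,
#'   `fraction` (`NaN` with `n_peaks = 0` for empty classes).
#' @export
motif_census <- function(peaks, genome, classes,
                         patterns = core_promoter_patterns(),
                         width = 75L, strands = "both") {
  all_ids <- unique(unlist(classes, use.names = FALSE))
  sel <- peaks[match(all_ids, peaks$peak_id), , drop = FALSE]
  if (any(is.na(sel$peak_id)))
    stop("class peak id not found in peak set: ",
         all_ids[which(is.na(sel$peak_id))[1]])
  hit <- sapply(patterns$pattern, function(p)
    peak_has_motif(sel, genome, p, width, strands))
  hit <- matrix(hit, nrow = nrow(sel),
                dimnames = list(sel$peak_id, patterns$name))
  out <- expand.grid(class = names(classes), pattern = patterns$name,
                     stringsAsFactors = FALSE)
  out$n_peaks <- vapply(out$class, function(cl)
    length(classes[[cl]]), integer(1))
  out$n_with_match <- mapply(function(cl, pat)
    sum(hit[classes[[cl]], pat]), out$class, out$pattern)
  out$fraction <- out$n_with_match / out$n_peaks
  out[order(out$class, out$pattern), , drop = FALSE]
}

#' Standard census classes from a peak partition
#'
#' Builds the class lists the census reports on: expressed and silent peaks
#' within the TSS limit, plus the upstream/downstream split of the expressed
#' proximal subset. Peaks beyond the limit are excluded throughout.
#'
#' @param partition output of [partition_peaks()].
#' @param tss_limit bp; only peaks with `|signed_distance| <= tss_limit`
#'   enter the census. Default 1000.
#' @return Named list of peak-id vectors.
#' @export
census_classes <- function(partition, tss_limit = 1000L) {
  p <- partition$peaks
  near <- !is.na(p$signed_distance) & abs(p$signed_distance) <= tss_limit
  list(
    expressed_1kb = p$peak_id[near & p$expression == "expressed"],
    silent_1kb = p$peak_id[near & p$expression == "silent"],
    expressed_up_1kb = p$peak_id[near & p$expression == "expressed" &
                                   p$signed_distance < 0],
    expressed_down_1kb = p$peak_id[near & p$expression == "expressed" &
                                     p$signed_distance >= 0])
}

#' BRE enrichment tests
#'
#' Two Pearson chi-square tests on the BRE (TFII-B recognition element)
#' census counts: whether BRE-bearing peaks are overrepresented among
#' TSS-proximal peaks relative to all peaks considered, and whether proximal
#' BRE-bearing peaks preferentially sit at active (expressed) genes.
#'
#' @param proximal_with,proximal_n BRE-bearing and total proximal peaks.
#' @param all_with,all_n BRE-bearing and total peaks in the full comparison
#'   set (proximal + non-proximal); the non-proximal cell is the difference.
#' @param active_with,active_n,silent_with,silent_n BRE counts among proximal
#'   peaks at expressed and at silent genes.
#' @return List of two [chisq_2x2()] results: `proximal_vs_all`,
#'   `active_vs_silent`.
#' @export
bre_enrichment <- function(proximal_with, proximal_n, all_with, all_n,
                           active_with, active_n, silent_with, silent_n) {
  t1 <- matrix(c(proximal_with, proximal_n - proximal_with,
                 all_with - proximal_with,
                 (all_n - proximal_n) - (all_with - proximal_with)),
               nrow = 2,
               dimnames = list(c("with_BRE", "without_BRE"),
                               c("proximal", "non_proximal")))
  t2 <- matrix(c(active_with, active_n - active_with,
                 silent_with, silent_n - silent_with),
               nrow = 2,
               dimnames = list(c("with_BRE", "without_BRE"),
                               c("active", "silent")))
  list(proximal_vs_all = chisq_2x2(t1), active_vs_silent = chisq_2x2(t2))
}
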