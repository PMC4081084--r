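# Co-occupancy: percentage of peaks in each class overlapping an external
# peak set within a gap tolerance (default 150 nt).

#' Do two peaks lie within a gap tolerance of one another?
#'
#' True iff the peaks share a chromosome and the edge gap between the
#' intervals is at most `maxgap`, where
#' `gap = max(b_start - a_end, a_start - b_end, 0)`; intersecting intervals
#' have gap 0 and the boundary is inclusive (gap exactly `maxgap` counts).
#'
#' @param a,b single-row peak `data.frame`s (or lists with `chrom`, `start`,
#'   `end`).
#' @param maxgap non-negative gap tolerance in nt, default 150.
#' @return Logical scalar.
#' @export
overlaps_within <- function(a, b, maxgap = 150L) {
  stopifnot(maxgap >= 0)
  if (a$chrom != b$chrom) return(FALSE)
  gap <- max(b$start - a$end, a$start - b$end, 0L)
  gap <= maxgap
}

.peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$start + 1L, peaks$end))
}

# Summit-distance mode: fixed 1-bp anchors at each peak's reference point.
.points_to_granges <- function(peaks) {
  pt <- reference_point(peaks)
  GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(pt + 1L, pt + 1L))
}

#' Fraction of peaks overlapping an external set within a gap tolerance
#'
#' `100 * |{a in class : some b in set within maxgap}| / |class|`. Each peak
#' counts at most once however many external peaks it touches. In
#' `"interval"` mode (default) whole peak intervals are compared; in
#' `"summit"` mode the comparison uses 1-bp anchors at each peak's reference
#' point, so `maxgap` becomes a summit-distance tolerance.
#'
#' @param class_peaks peak `data.frame` for the class (the denominator).
#' @param set_peaks external peak `data.frame`.
#' @param maxgap gap tolerance in nt, default 150.
#' @param mode `"interval"` or `"summit"`.
#' @return List with `percent` (`NA` for an empty class, flagged via
#'   `undefined`), `n_overlap`, `n_total`, `undefined`.
#' @export
overlap_fraction <- function(class_peaks, set_peaks, maxgap = 150L,
                             mode = c("interval", "summit")) {
  mode <- match.arg(mode)
  stopifnot(maxgap >= 0)
  n <- nrow(class_peaks)
  if (n == 0)
    return(list(percent = NA_real_, n_overlap = 0L, n_total = 0L,
                undefined = TRUE))
  if (nrow(set_peaks) == 0)
    return(list(percent = 0, n_overlap = 0L, n_total = n, undefined = FALSE))
  conv <- if (mode == "interval") .peaks_to_granges else .points_to_granges
  # disjoint seqlevels (all peaks on other chromosomes) is a valid 0% case
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(conv(class_peaks), conv(set_peaks),
                                 maxgap = maxgap)) > 0
  list(percent = 100 * sum(hits) / n, n_overlap = sum(hits),
       n_total = n, undefined = FALSE)
}

#' Overlap-percentage matrix: peak classes x external peak sets
#'
#' Rows are peak classes (by default the six analysis classes: expressed,
#' silent, proximal, distal, proximal-upstream, proximal-downstream), columns
#' are external sets; each cell is the percentage of class peaks with an
#' external peak within `maxgap`. Percentages are row-normalised by class
#' size.
#'
#' @param peaks peak `data.frame` holding every classed peak.
#' @param classes named list of peak-id vectors (e.g. from
#'   [standard_classes()]).
#' @param external named list of peak `data.frame`s.
#' @param maxgap gap tolerance in nt, default 150.
#' @param mode `"interval"` (default) or `"summit"`, see
#'   [overlap_fraction()].
#' @return List with `percent` (matrix), `n_overlap` (matrix), `n_class`
#'   (named vector of denominators).
#' @export
overlap_matrix <- function(peaks, classes, external, maxgap = 150L,
                           mode = "interval") {
  if (is.null(names(classes)) || is.null(names(external)))
    stop("classes and external sets must be named")
  pct <- matrix(NA_real_, nrow = length(classes), ncol = length(external),
                dimnames = list(names(classes), names(external)))
  num <- pct
  for (cl in names(classes)) {
    idx <- match(classes[[cl]], peaks$peak_id)
    if (any(is.na(idx))) stop("unknown peak id in class ", cl)
    sub <- peaks[idx, , drop = FALSE]
    for (ex in names(external)) {
      r <- overlap_fraction(sub, external[[ex]], maxgap, mode)
      pct[cl, ex] <- r$percent
      num[cl, ex] <- r$n_overlap
    }
  }
  list(percent = pct, n_overlap = num,
       n_class = vapply(classes, length, integer(1)))
}

#' The six standard analysis classes of a peak partition
#'
#' @param partition output of [partition_peaks()].
#' @return Named list of peak-id vectors: `expressed`, `silent`, `proximal`,
#'   `distal`, `proximal_upstream`, `proximal_downstream`.
#' @export
standard_classes <- function(partition) {
  p <- partition$peaks
  list(
    expressed = p$peak_id[p$expression == "expressed"],
    silent = p$peak_id[p$expression == "silent"],
    proximal = p$peak_id[p$proximity == "proximal"],
    distal = p$peak_id[p$proximity == "distal"],
    proximal_upstream = p$peak_id[p$proximity == "proximal" &
                                    p$orientation == "upstream"],
    proximal_downstream = p$peak_id[p$proximity == "proximal" &
                                      p$orientation == "downstream"])
}
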