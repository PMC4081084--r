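# Peak-to-gene annotation: nearest gene by |TSS distance|, signed distances,
# genic-location and proximity classification, TSS-window histograms.

#' Reference point of a peak
#'
#' The single base used to anchor distance and motif-window calculations:
#' the summit when one is recorded, otherwise the interval midpoint
#' (`floor((start + end) / 2)`).
#'
#' @param peaks peak `data.frame` (see [read_peaks()]).
#' @return Integer vector of 0-based genomic positions.
#' @export
reference_point <- function(peaks) {
  mid <- (peaks$start + peaks$end) %/% 2L
  as.integer(ifelse(is.na(peaks$summit_offset), mid,
                    peaks$start + peaks$summit_offset))
}

#' Signed strand-aware distance from a point to a gene's TSS
#'
#' Negative values are upstream of the TSS, positive downstream, in the
#' gene's reading direction: `point - tss` on the plus strand, `tss - point`
#' on the minus strand. Zero iff the point is the TSS base itself.
#'
#' @param point integer vector of genomic positions (0-based).
#' @param tss integer vector of TSS positions.
#' @param strand character vector of `"+"`/`"-"`.
#' @param chrom_point,chrom_gene optional chromosome names; if both given,
#'   a mismatch is an error.
#' @return Integer vector of signed distances in bp.
#' @export
signed_tss_distance <- function(point, tss, strand,
                                chrom_point = NULL, chrom_gene = NULL) {
  if (!is.null(chrom_point) && !is.null(chrom_gene) &&
      any(chrom_point != chrom_gene))
    stop("point and gene are on different chromosomes")
  as.integer(ifelse(strand == "+", point - tss, tss - point))
}

# Nearest TSS for a vector of points on one chromosome.
# Returns the row index (into `genes`) of the chosen gene for each point:
# minimal |point - tss|, ties broken by lexicographically smallest gene_id.
.nearest_tss_one_chrom <- function(point, genes) {
  u <- sort(unique(genes$tss))
  idx <- findInterval(point, u)
  left <- ifelse(idx >= 1L, u[pmax(idx, 1L)], NA_integer_)
  right <- ifelse(idx < length(u), u[pmin(idx + 1L, length(u))], NA_integer_)
  dl <- abs(point - left)
  dr <- abs(right - point)
  dmin <- pmin(dl, dr, na.rm = TRUE)
  vapply(seq_along(point), function(i) {
    pos <- c(if (!is.na(left[i]) && dl[i] == dmin[i]) left[i],
             if (!is.na(right[i]) && dr[i] == dmin[i]) right[i])
    cand <- which(genes$tss %in% pos)
    cand[order(genes$gene_id[cand])][1L]
  }, integer(1))
}

#' Assign each peak to its nearest gene
#'
#' Nearest means minimal absolute TSS distance from the peak's reference
#' point, among genes on the same chromosome; ties are broken by the
#' lexicographically smallest `gene_id`, making the result independent of
#' input ordering. Peaks on chromosomes with no annotated gene get
#' `gene_id = "unassigned"`.
#'
#' @param peaks peak `data.frame`.
#' @param genes gene-model `data.frame` (see [gene_models()]).
#' @param proximal_threshold bp; `|distance| <= threshold` is proximal
#'   (boundary inclusive). Default 1000.
#' @param flag_distance bp; peaks farther than this from any TSS are flagged
#'   (`far` column), mirroring the 10 kb restriction used for motif input.
#' @return A `data.frame` with one row per peak: `peak_id`, `chrom`, `point`,
#'   `gene_id`, `signed_distance`, `location`
#'   (`TSS`/`TES`/`intragenic`/`upstream`/`downstream`), `proximity`
#'   (`proximal`/`distal`), `far` (logical).
#' @export
assign_nearest_gene <- function(peaks, genes, proximal_threshold = 1000L,
                                flag_distance = 10000L) {
  stopifnot(proximal_threshold > 0)
  n <- nrow(peaks)
  point <- reference_point(peaks)
  gene_row <- rep(NA_integer_, n)
  for (ch in unique(peaks$chrom)) {
    gsel <- which(genes$chrom == ch)
    psel <- which(peaks$chrom == ch)
    if (length(gsel) == 0) next
    gene_row[psel] <- gsel[.nearest_tss_one_chrom(point[psel],
                                                  genes[gsel, , drop = FALSE])]
  }
  assigned <- !is.na(gene_row)
  g <- genes[ifelse(assigned, gene_row, 1L), , drop = FALSE]
  d <- signed_tss_distance(point, g$tss, g$strand)
  loc <- classify_genic_location(peaks, g, d)
  out <- data.frame(
    peak_id = peaks$peak_id, chrom = peaks$chrom, point = point,
    gene_id = ifelse(assigned, g$gene_id, "unassigned"),
    signed_distance = ifelse(assigned, d, NA_integer_),
    location = ifelse(assigned, loc, NA_character_),
    proximity = ifelse(assigned,
                       proximity_class(d, proximal_threshold), NA_character_),
    far = ifelse(assigned, abs(d) > flag_distance, NA),
    stringsAsFactors = FALSE)
  out
}

#' Classify a peak's location relative to its assigned gene
#'
#' Categories, in precedence order: `TSS` if the peak interval contains the
#' TSS base; `TES` if it contains the TES base; `intragenic` if the interval
#' lies within the gene span; otherwise `upstream` (signed distance < 0) or
#' `downstream` (> 0).
#'
#' @param peaks peak `data.frame` rows.
#' @param genes matching gene-model rows (the assigned nearest gene per peak).
#' @param signed_distance precomputed signed distances (optional; recomputed
#'   from the reference point when missing).
#' @return Character vector of location categories.
#' @export
classify_genic_location <- function(peaks, genes, signed_distance = NULL) {
  if (is.null(signed_distance))
    signed_distance <- signed_tss_distance(reference_point(peaks),
                                           genes$tss, genes$strand)
  has_tss <- peaks$start <= genes$tss & genes$tss < peaks$end
  has_tes <- peaks$start <= genes$tes & genes$tes < peaks$end
  inside <- peaks$start >= genes$span_start & peaks$end <= genes$span_end
  ifelse(has_tss, "TSS",
         ifelse(has_tes, "TES",
                ifelse(inside, "intragenic",
                       ifelse(signed_distance < 0, "upstream", "downstream"))))
}

#' Proximal/distal classification of a TSS distance
#'
#' Proximal iff `|signed_distance| <= threshold`; the boundary is inclusive
#' (a peak exactly 1 kb from the TSS is proximal).
#'
#' @param signed_distance integer vector of signed distances in bp.
#' @param threshold positive bp threshold (default 1000).
#' @return Character vector, `"proximal"` or `"distal"`.
#' @export
proximity_class <- function(signed_distance, threshold = 1000L) {
  stopifnot(threshold > 0)
  ifelse(abs(signed_distance) <= threshold, "proximal", "distal")
}

#' TSS-distance histogram by expression class
#'
#' Bins the signed TSS distances of peaks into half-open bins
#' `[lo, lo + bin)` covering `[-window, +window]`, separately for each
#' expression class; a distance exactly `+window` is counted in the last bin.
#' Also returns per-class densities (counts normalised to sum to 1).
#'
#' @param signed_distance integer vector of signed distances.
#' @param class character vector of class labels (e.g. expressed/silent),
#'   same length.
#' @param window half-width of the profile in bp (default 2000).
#' @param bin bin width in bp; must divide `2 * window`. Default 100.
#' @return `data.frame` with `bin_lo`, `bin_hi`, then one `count_<class>` and
#'   one `density_<class>` column per class level.
#' @export
tss_window_profile <- function(signed_distance, class,
                               window = 2000L, bin = 100L) {
  if ((2L * window) %% bin != 0L) stop("bin must divide 2 * window")
  edges <- seq(-window, window, by = bin)
  lo <- edges[-length(edges)]
  out <- data.frame(bin_lo = lo, bin_hi = lo + bin)
  keep <- !is.na(signed_distance) & abs(signed_distance) <= window
  d <- signed_distance[keep]
  cls <- class[keep]
  idx <- pmin(((d + window) %/% bin) + 1L, length(lo))  # +window -> last bin
  for (cl in sort(unique(class))) {
    counts <- tabulate(idx[cls == cl], nbins = length(lo))
    out[[paste0("count_", cl)]] <- counts
    tot <- sum(counts)
    out[[paste0("density_", cl)]] <- if (tot > 0) counts / tot else counts * 0
  }
  out
}
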