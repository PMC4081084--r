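# Expression stratification: label genes expressed/silent at an RPKM cutoff,
# partition peaks into the analysis classes, and summarise unique target genes.

#' Label genes expressed or silent at an RPKM cutoff
#'
#' A gene is `expressed` iff `rpkm >= cutoff` (boundary inclusive), `silent`
#' iff below. Genes absent from the expression table are `unknown` when later
#' joined against assignments.
#'
#' @param expr expression `data.frame` (`gene_id`, `rpkm`).
#' @param cutoff RPKM threshold, default 1.
#' @return Named character vector mapping `gene_id` to
#'   `"expressed"`/`"silent"`.
#' @export
label_expressed <- function(expr, cutoff = 1.0) {
  stopifnot(cutoff >= 0)
  if (any(expr$rpkm < 0)) stop("rpkm values must be non-negative")
  stats::setNames(ifelse(expr$rpkm >= cutoff, "expressed", "silent"),
                  expr$gene_id)
}

#' Expression status of each peak's target gene
#'
#' @param assignments output of [assign_nearest_gene()].
#' @param labels named vector from [label_expressed()].
#' @param unknown_as_silent treat genes missing from the expression table as
#'   silent instead of `unknown`. Default `FALSE`.
#' @return Character vector (`expressed`/`silent`/`unknown`) per peak.
#' @export
expression_status <- function(assignments, labels, unknown_as_silent = FALSE) {
  st <- unname(labels[assignments$gene_id])
  st[is.na(st) | assignments$gene_id == "unassigned"] <-
    if (unknown_as_silent) "silent" else "unknown"
  st
}

#' Partition peaks into expression / proximity / orientation classes
#'
#' Each peak is labelled by its target gene's expression status
#' (`expressed`/`silent`/`unknown`), its own TSS proximity
#' (`proximal`/`distal`), and — for proximal peaks — its orientation relative
#' to the TSS (`upstream` for negative signed distance, `downstream` for
#' positive; a distance of exactly 0 means the reference point is the TSS
#' base itself and counts as downstream).
#'
#' @inheritParams expression_status
#' @param proximal_threshold bp threshold for proximal (inclusive),
#'   default 1000.
#' @return A list with `peaks` (per-peak `data.frame` adding `expression`,
#'   `proximity`, `orientation`) and `counts` (named integer vector with
#'   `total`, `expressed`, `silent`, `unknown`, `proximal`, `distal`,
#'   `proximal_upstream`, `proximal_downstream`).
#' @export
partition_peaks <- function(assignments, labels, proximal_threshold = 1000L,
                            unknown_as_silent = FALSE) {
  st <- expression_status(assignments, labels, unknown_as_silent)
  d <- assignments$signed_distance
  prox <- ifelse(is.na(d), "distal", proximity_class(d, proximal_threshold))
  orient <- ifelse(prox == "proximal",
                   ifelse(d < 0, "upstream", "downstream"), NA_character_)
  tab <- cbind(assignments,
               data.frame(expression = st, proximity = prox,
                          orientation = orient, stringsAsFactors = FALSE))
  counts <- c(
    total = nrow(tab),
    expressed = sum(st == "expressed"),
    silent = sum(st == "silent"),
    unknown = sum(st == "unknown"),
    proximal = sum(prox == "proximal"),
    distal = sum(prox == "distal"),
    proximal_upstream = sum(prox == "proximal" & orient == "upstream"),
    proximal_downstream = sum(prox == "proximal" & orient == "downstream"))
  list(peaks = tab, counts = counts)
}

#' Summarise unique target genes by expression status
#'
#' Deduplicates the assigned gene ids and splits them by expression status,
#' with integer-rounded percentage shares.
#'
#' @inheritParams expression_status
#' @return A list with `counts` (named integer vector over
#'   expressed/silent/unknown plus `total`) and `share_pct` (integer-rounded
#'   percentages of total).
#' @export
summarize_target_genes <- function(assignments, labels,
                                   unknown_as_silent = FALSE) {
  ids <- unique(assignments$gene_id[assignments$gene_id != "unassigned"])
  st <- unname(labels[ids])
  st[is.na(st)] <- if (unknown_as_silent) "silent" else "unknown"
  counts <- c(expressed = sum(st == "expressed"),
              silent = sum(st == "silent"),
              unknown = sum(st == "unknown"),
              total = length(ids))
  list(counts = counts, share_pct = target_share_pct(counts))
}

#' Integer-rounded percentage shares of target-gene counts
#'
#' @param counts named vector with `expressed`, `silent` (and optionally
#'   `unknown`) counts; `total` is recomputed from the parts so the shares
#'   are internally consistent.
#' @return Named vector of percentages rounded to the nearest integer.
#' @export
target_share_pct <- function(counts) {
  parts <- counts[names(counts) %in% c("expressed", "silent", "unknown")]
  parts <- parts[parts > 0 | names(parts) %in% c("expressed", "silent")]
  total <- sum(parts)
  if (total == 0) return(stats::setNames(rep(0, length(parts)), names(parts)))
  round(100 * parts / total)
}
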