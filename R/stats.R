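# Enrichment and distribution tests: 2x2 Pearson chi-square, two-sample
# Wilcoxon rank-sum, Wilson score intervals, and an optional BH utility.

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Pearson statistic with 1 degree of freedom and an upper-tail p-value.
#' The Yates continuity correction is off by default.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param continuity_correction apply the Yates correction. Default `FALSE`.
#' @return A list (`statistic`, `p_value`, `df`, `method`, `table`).
#' @examples
#' chisq_2x2(matrix(c(20, 10, 10, 20), 2))$statistic  # ~6.667
#' @export
chisq_2x2 <- function(table, continuity_correction = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal: chi-square undefined, consider an exact test")
  # the small-expected-count warning concerns the asymptotic approximation;
  # the Pearson statistic itself is exact arithmetic
  res <- suppressWarnings(
    stats::chisq.test(table, correct = continuity_correction))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value),
       df = 1L,
       method = if (continuity_correction)
         "Pearson chi-square (Yates)" else "Pearson chi-square",
       table = table)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact p-value by enumeration when `n + m <= 12` and the pooled sample has
#' no ties; otherwise the normal approximation with tie and continuity
#' corrections. Two-sided by default.
#'
#' @param x,y non-empty numeric samples.
#' @param two_sided two-sided alternative (default); otherwise the p-value
#'   for `x` shifted left of `y`.
#' @return A list (`statistic` = Mann-Whitney U for `x`, `p_value`, `n`, `m`,
#'   `method`).
#' @export
wilcoxon_rank_sum <- function(x, y, two_sided = TRUE) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  n <- length(x); m <- length(y)
  exact <- (n + m <= 12L) && !anyDuplicated(c(x, y))
  res <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = if (two_sided) "two.sided" else "less",
    exact = exact, correct = TRUE))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value),
       n = n, m = m,
       method = if (exact) "Wilcoxon rank-sum (exact)"
                else "Wilcoxon rank-sum (normal approximation)")
}

#' Wilson score confidence interval for a proportion
#'
#' @param successes,trials non-negative counts with
#'   `0 <= successes <= trials`, `trials > 0`.
#' @param level confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)`, contained in `[0, 1]`.
#' @export
proportion_ci <- function(successes, trials, level = 0.95) {
  if (trials <= 0 || successes < 0 || successes > trials)
    stop("need 0 <= successes <= trials, trials > 0")
  ci <- suppressWarnings(
    stats::prop.test(successes, trials, conf.level = level,
                     correct = FALSE)$conf.int)
  c(lower = ci[1], upper = ci[2])
}

#' Benjamini-Hochberg adjustment (optional utility)
#'
#' Raw p-values are reported throughout the pipeline; this helper is provided
#' for users who want FDR control across a family of tests.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")

# Text rendering convention: p-values below the double-precision floor are
# printed "< 2.2e-16"; JSON output keeps the raw float.
format_p <- function(p) {
  ifelse(p < 2.2e-16, "< 2.2e-16", formatC(p, format = "g", digits = 4))
}
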