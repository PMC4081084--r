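# Top-level pipeline: annotate -> stratify -> stats -> motifs (optional)
# -> co-occupancy (optional), with TSV tables and a JSON report.

#' Pipeline configuration
#'
#' Inputs may be file paths (read through the package's readers) or
#' already-loaded objects. `fasta`/`genome` and `marks` are optional; the
#' corresponding report sections are omitted when absent.
#'
#' @param peaks peak file path or peak `data.frame`.
#' @param genes gene-model file path or `data.frame`.
#' @param expression expression file path or `data.frame`.
#' @param fasta optional genome FASTA path (or named character vector via
#'   `genome`).
#' @param genome optional in-memory genome (overrides `fasta`).
#' @param marks optional named character vector of external peak files, or
#'   named list of peak `data.frame`s.
#' @param peaks_format,marks_format `"narrowPeak"` (default) or `"bed"`.
#' @param genes_format `"tsv"` (default) or `"gtf"`.
#' @param proximal_threshold,profile_window,profile_bin,motif_width,tss_limit,flag_distance,rpkm_cutoff,maxgap
#'   analysis thresholds in bp/nt; defaults are the standard values
#'   (1 kb proximal, 2 kb profile, 100 bp bins, 75 nt windows, 1 kb census
#'   limit, 10 kb far flag, RPKM 1, 150 nt overlap gap).
#' @param unknown_as_silent treat genes missing from the expression table as
#'   silent. Default `FALSE` (excluded from expressed-vs-silent tests).
#' @param overlap_mode `"interval"` or `"summit"` co-occupancy mode.
#' @param seed recorded in the report for provenance (the pipeline itself is
#'   deterministic).
#' @return A config list of class `pipeline_config`.
#' @export
pipeline_config <- function(peaks, genes, expression,
                            fasta = NULL, genome = NULL, marks = NULL,
                            peaks_format = "narrowPeak",
                            genes_format = "tsv",
                            marks_format = "narrowPeak",
                            proximal_threshold = 1000L,
                            profile_window = 2000L, profile_bin = 100L,
                            motif_width = 75L, tss_limit = 1000L,
                            flag_distance = 10000L, rpkm_cutoff = 1.0,
                            maxgap = 150L, unknown_as_silent = FALSE,
                            overlap_mode = "interval", seed = NA_integer_) {
  cfg <- as.list(environment())
  if (missing(peaks) || missing(genes) || missing(expression))
    stop("configuration error: peaks, genes and expression are required")
  for (f in c("peaks", "genes", "expression"))
    if (is.character(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configuration error: ", f, " file not found: ", cfg[[f]])
  if (!is.null(cfg$fasta) && !file.exists(cfg$fasta))
    stop("configuration error: fasta file not found: ", cfg$fasta)
  if (is.character(cfg$marks))
    for (m in cfg$marks) if (!file.exists(m))
      stop("configuration error: mark file not found: ", m)
  class(cfg) <- "pipeline_config"
  cfg
}

.safe_chisq <- function(table) {
  tryCatch(chisq_2x2(table), error = function(e)
    list(statistic = NA_real_, p_value = NA_real_, df = 1L,
         method = "Pearson chi-square (not computable)", table = table,
         note = conditionMessage(e)))
}

.safe_wilcox <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_,
                n = length(x), m = length(y),
                method = "Wilcoxon rank-sum (empty sample)"))
  wilcoxon_rank_sum(x, y)
}

#' Run the full downstream analysis
#'
#' Executes annotation, expression stratification, the distribution and
#' enrichment tests, the core-promoter motif census (when a genome is given)
#' and the co-occupancy matrix (when external mark sets are given). When
#' `out` is set, writes per-stage TSV tables and a single `report.json`;
#' repeated runs with the same inputs produce byte-identical reports.
#'
#' @param config a [pipeline_config()].
#' @param out optional output directory.
#' @param verbose log thresholds and stage progress via `message()`.
#' @return The report as a nested list (invisibly identical to the JSON).
#' @export
run_analysis <- function(config, out = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  peaks <- if (is.character(config$peaks))
    read_peaks(config$peaks, config$peaks_format) else config$peaks
  genes <- if (is.character(config$genes))
    read_gene_models(config$genes, config$genes_format) else config$genes
  expr <- if (is.character(config$expression))
    read_expression(config$expression) else config$expression
  genome <- config$genome
  if (is.null(genome) && !is.null(config$fasta))
    genome <- read_genome(config$fasta)
  marks <- config$marks
  if (is.character(marks))
    marks <- lapply(marks, read_peaks, format = config$marks_format)
  params <- config[c("proximal_threshold", "profile_window", "profile_bin",
                     "motif_width", "tss_limit", "flag_distance",
                     "rpkm_cutoff", "maxgap", "unknown_as_silent",
                     "overlap_mode", "seed")]
  say("thresholds: ", paste(names(params), unlist(params), sep = "=",
                            collapse = " "))

  say("annotating ", nrow(peaks), " peaks against ", nrow(genes), " genes")
  asg <- assign_nearest_gene(peaks, genes, config$proximal_threshold,
                             config$flag_distance)
  loc_counts <- vapply(c("TSS", "TES", "intragenic", "upstream",
                         "downstream"),
                       function(l) sum(asg$location == l, na.rm = TRUE),
                       integer(1))
  labels <- label_expressed(expr, config$rpkm_cutoff)
  part <- partition_peaks(asg, labels, config$proximal_threshold,
                          config$unknown_as_silent)
  targets <- summarize_target_genes(asg, labels, config$unknown_as_silent)

  p <- part$peaks
  inwin <- !is.na(p$signed_distance) &
    abs(p$signed_distance) <= config$profile_window &
    p$expression %in% c("expressed", "silent")
  profile <- tss_window_profile(p$signed_distance[inwin],
                                p$expression[inwin],
                                config$profile_window, config$profile_bin)
  # downstream-abundance test over the profile window
  tab <- table(factor(ifelse(p$signed_distance[inwin] < 0,
                             "upstream", "downstream"),
                      levels = c("upstream", "downstream")),
               factor(p$expression[inwin],
                      levels = c("expressed", "silent")))
  downstream_test <- .safe_chisq(unclass(tab))
  up <- inwin & p$signed_distance < 0
  dn <- inwin & p$signed_distance >= 0
  wil_up <- .safe_wilcox(abs(p$signed_distance[up & p$expression ==
                                                 "expressed"]),
                         abs(p$signed_distance[up & p$expression ==
                                                 "silent"]))
  wil_dn <- .safe_wilcox(abs(p$signed_distance[dn & p$expression ==
                                                 "expressed"]),
                         abs(p$signed_distance[dn & p$expression ==
                                                 "silent"]))

  report <- list(
    params = params,
    annotation = list(
      n_peaks = nrow(peaks),
      location_counts = as.list(loc_counts),
      intergenic = unname(loc_counts["upstream"] +
                            loc_counts["downstream"]),
      n_far = sum(asg$far, na.rm = TRUE)),
    stratification = list(
      class_counts = as.list(part$counts),
      target_genes = list(counts = as.list(targets$counts),
                          share_pct = as.list(targets$share_pct))),
    profile = as.list(profile),
    stats = list(downstream_abundance = downstream_test,
                 wilcoxon_upstream = wil_up,
                 wilcoxon_downstream = wil_dn))

  census <- NULL
  if (!is.null(genome)) {
    say("motif census over summit windows")
    classes <- census_classes(part, config$tss_limit)
    census <- motif_census(peaks, genome, classes,
                           width = config$motif_width)
    # BRE enrichment: proximal (<= tss_limit) vs all peaks within the far
    # flag distance, and active vs silent among proximal peaks
    near10 <- p$peak_id[!is.na(p$signed_distance) &
                          abs(p$signed_distance) <= config$flag_distance]
    prox <- p$peak_id[!is.na(p$signed_distance) &
                        abs(p$signed_distance) <= config$tss_limit]
    bre_all <- motif_census(peaks, genome,
                            list(all_10kb = near10, proximal = prox),
                            patterns = data.frame(name = "BRE",
                                                  pattern = "SSRCGCC"),
                            width = config$motif_width)
    ce <- function(df, cl) df[df$class == cl, ]
    exp1 <- ce(census, "expressed_1kb")[ce(census, "expressed_1kb")$pattern
                                        == "BRE", ]
    sil1 <- ce(census, "silent_1kb")[ce(census, "silent_1kb")$pattern
                                     == "BRE", ]
    pr <- ce(bre_all, "proximal"); al <- ce(bre_all, "all_10kb")
    bre <- tryCatch(
      bre_enrichment(pr$n_with_match, pr$n_peaks,
                     al$n_with_match, al$n_peaks,
                     exp1$n_with_match, exp1$n_peaks,
                     sil1$n_with_match, sil1$n_peaks),
      error = function(e) list(note = conditionMessage(e)))
    report$motifs <- list(census = as.list(census), bre_enrichment = bre)
  }

  ovl <- NULL
  if (!is.null(marks) && length(marks) > 0) {
    say("co-occupancy against ", length(marks), " mark sets")
    classes6 <- standard_classes(part)
    ovl <- overlap_matrix(peaks, classes6, marks, config$maxgap,
                          config$overlap_mode)
    report$cooccupancy <- list(
      percent = apply(ovl$percent, 1, as.list),
      n_overlap = apply(ovl$n_overlap, 1, as.list),
      n_class = as.list(ovl$n_class))
  }

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(p, file.path(out, "assignments.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(profile, file.path(out, "profile.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(census))
      utils::write.table(census, file.path(out, "census.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (!is.null(ovl))
      utils::write.table(cbind(class = rownames(ovl$percent),
                               as.data.frame(ovl$percent)),
                         file.path(out, "overlap_matrix.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null", null = "null")
  }
  invisible(report)
}
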