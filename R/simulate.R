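# Synthetic-data generator: genomes, gene models, expression tables, TF peak
# sets and mark sets with the statistical structure the analysis assumes,
# plus a ground-truth ledger recording every planted signal.
#
# Each artifact draws from its own RNG stream (master seed + a fixed small
# offset), so regenerating one artifact does not perturb the others.

.SEED_SEQUENCE <- 1L
.SEED_GENES <- 2L
.SEED_PEAKS <- 3L
.SEED_MOTIFS <- 4L
.SEED_EXPRESSION <- 5L
.SEED_MARKS <- 6L

#' Simulation configuration
#'
#' Defaults define the study conditions every recovery test runs under:
#' 4 chromosomes of 2 Mb; 400 genes of 2-20 kb spaced at least 2 kb apart;
#' half the genes expressed; 2500 peaks of which 80% are TSS-linked
#' (about 1000 linked peaks per expression class); summit offsets from the
#' linked TSS drawn from truncated normals on [-10 kb, 10 kb] - N(-300, 400)
#' at expressed genes (upstream bias), N(0, 800) at silent genes; TATA boxes
#' planted in 40%/10% of expressed/silent summit windows and BRE in 30%/5%
#' of proximal/distal windows; two mark sets co-occupying TF peaks with
#' probability 0.5 and 0.2 over 5 background peaks per Mb.
#'
#' @param seed master integer seed; per-artifact streams are derived from it.
#' @param n_chrom,chrom_length genome shape.
#' @param n_genes number of genes (split evenly across chromosomes).
#' @param gene_length `c(min, max)` gene length in bp.
#' @param gene_spacing minimum gap between adjacent genes, bp.
#' @param frac_expressed probability a gene is expressed.
#' @param n_peaks,frac_tss_linked TF peak count and the probability a peak is
#'   attached to a gene TSS rather than placed in gene-free background.
#' @param offset_expressed,offset_silent `c(mean, sd)` of the signed
#'   TSS-offset model (bp) per target-gene class.
#' @param offset_trunc truncation half-width of the offset models, bp.
#' @param peak_width `c(min, max)` peak width in bp.
#' @param rpkm_cutoff expression threshold; draws are kept on the correct
#'   side of it so ledger class labels are exact.
#' @param expr_meanlog,expr_sdlog,silent_meanlog,silent_sdlog log-normal
#'   RPKM parameters for expressed (median 10) and silent (median 0.1) genes.
#' @param boundary_mode place a fraction of expressed genes at exactly the
#'   cutoff to exercise the inclusive-boundary rule. Default `FALSE`.
#' @param plant_rates `data.frame(pattern, class, rate)`; `class` is one of
#'   `expressed`, `silent` (target-gene class) or `proximal`, `distal`
#'   (|offset| vs 1 kb).
#' @param marks named list; each element `list(q =, background_per_mb =)`.
#' @param mark_jitter maximum |shift| of a seeded mark summit from the TF
#'   summit, bp.
#' @return A validated config list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 4L, chrom_length = 2e6,
                       n_genes = 400L, gene_length = c(2000L, 20000L),
                       gene_spacing = 2000L,
                       frac_expressed = 0.5,
                       n_peaks = 2500L, frac_tss_linked = 0.8,
                       offset_expressed = c(mean = -300, sd = 400),
                       offset_silent = c(mean = 0, sd = 800),
                       offset_trunc = 10000L,
                       peak_width = c(150L, 400L),
                       rpkm_cutoff = 1.0,
                       expr_meanlog = log(10), expr_sdlog = 1,
                       silent_meanlog = log(0.1), silent_sdlog = 1,
                       boundary_mode = FALSE,
                       plant_rates = default_plant_rates(),
                       marks = list(mark_A = list(q = 0.5,
                                                  background_per_mb = 5),
                                    mark_B = list(q = 0.2,
                                                  background_per_mb = 5)),
                       mark_jitter = 100L) {
  cfg <- as.list(environment())
  probs <- c(frac_expressed, frac_tss_linked,
             if (nrow(plant_rates) > 0) plant_rates$rate,
             vapply(marks, function(m) m$q, numeric(1)))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (seed + 10L >= 2^31) stop("seed too large")
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_plant_rates <- function() {
  data.frame(pattern = c("TATAAA", "TATAAA", "SSRCGCC", "SSRCGCC"),
             class = c("expressed", "silent", "proximal", "distal"),
             rate = c(0.40, 0.10, 0.30, 0.05),
             stringsAsFactors = FALSE)
}

.chrom_names <- function(config) sprintf("chr%d", seq_len(config$n_chrom))

# Truncated normal by rejection (bands used here keep acceptance high).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a random genome sequence
#'
#' Uniform random ACGT per chromosome, deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return Named character vector of chromosome sequences.
#' @export
simulate_sequence <- function(config) {
  set.seed(config$seed + .SEED_SEQUENCE)
  chroms <- .chrom_names(config)
  stats::setNames(vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
          collapse = ""), character(1)), chroms)
}

#' Simulate non-overlapping gene models with expression classes
#'
#' Genes are split evenly across chromosomes and placed left to right with at
#' least `gene_spacing` bp between them, leftover space distributed as random
#' extra gaps; strands are assigned with equal probability. Each gene is
#' independently marked expressed with probability `frac_expressed` (the
#' truth label the expression table is later drawn to respect).
#'
#' @param config a [sim_config()].
#' @return List with `genes` (a [gene_models()] table) and `gene_truth`
#'   (`data.frame(gene_id, class)`).
#' @export
simulate_genes <- function(config) {
  set.seed(config$seed + .SEED_GENES)
  chroms <- .chrom_names(config)
  per <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1)))
  id_counter <- 0L
  rows <- list()
  for (ci in seq_along(chroms)) {
    n <- per[ci]
    if (n == 0) next
    len <- sample(seq(config$gene_length[1], config$gene_length[2]), n,
                  replace = TRUE)
    need <- sum(len) + (n + 1L) * config$gene_spacing
    if (need > config$chrom_length)
      stop("infeasible packing: ", n, " genes need ", need,
           " bp on a ", config$chrom_length, " bp chromosome")
    free <- config$chrom_length - need
    # split the leftover into n+1 random gap increments
    cuts <- sort(stats::runif(n, 0, free))
    extra <- diff(c(0, cuts, free))
    gaps <- config$gene_spacing + extra
    start <- round(cumsum(gaps[seq_len(n)]) + c(0, cumsum(len[-n])))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("g%04d", id_counter + seq_len(n))
    id_counter <- id_counter + n
    rows[[ci]] <- data.frame(gene_id = ids, chrom = chroms[ci],
                             start = as.integer(start),
                             end = as.integer(start + len),
                             strand = strand, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  genes <- if (is.null(tab)) {
    gene_models(character(), character(), integer(), integer(), character())
  } else {
    gene_models(tab$gene_id, tab$chrom, tab$start, tab$end, tab$strand)
  }
  cls <- if (nrow(genes) > 0)
    ifelse(stats::runif(nrow(genes)) < config$frac_expressed,
           "expressed", "silent") else character(0)
  list(genes = genes,
       gene_truth = data.frame(gene_id = genes$gene_id, class = cls,
                               stringsAsFactors = FALSE))
}

#' Simulate an expression table consistent with the gene truth labels
#'
#' RPKM values are log-normal (median 10 for expressed genes, 0.1 for silent)
#' truncated at the cutoff so every gene lands on its true side of the
#' expressed/silent boundary. With `boundary_mode` a fifth of expressed genes
#' sit at exactly the cutoff, exercising the inclusive-boundary rule.
#'
#' @param config a [sim_config()].
#' @param gene_truth from [simulate_genes()].
#' @return Expression `data.frame` (`gene_id`, `rpkm`).
#' @export
simulate_expression <- function(config, gene_truth) {
  set.seed(config$seed + .SEED_EXPRESSION)
  n <- nrow(gene_truth)
  rpkm <- numeric(n)
  expressed <- gene_truth$class == "expressed"
  draw_trunc <- function(k, meanlog, sdlog, keep) {
    out <- numeric(0)
    while (length(out) < k) {
      x <- stats::rlnorm(k, meanlog, sdlog)
      out <- c(out, x[keep(x)])
    }
    out[seq_len(k)]
  }
  cut <- config$rpkm_cutoff
  rpkm[expressed] <- draw_trunc(sum(expressed), config$expr_meanlog,
                                config$expr_sdlog, function(x) x >= cut)
  rpkm[!expressed] <- draw_trunc(sum(!expressed), config$silent_meanlog,
                                 config$silent_sdlog, function(x) x < cut)
  if (config$boundary_mode && any(expressed)) {
    at <- which(expressed)
    at <- at[seq_len(max(1L, length(at) %/% 5L))]
    rpkm[at] <- cut
  }
  data.frame(gene_id = gene_truth$gene_id, rpkm = rpkm,
             stringsAsFactors = FALSE)
}

# Generator-side nearest-gene accounting: a deliberately naive scan over all
# same-chromosome genes, independent of the pipeline's indexed search. The
# ledger's class labels come from here.
.truth_nearest <- function(chrom, point, genes) {
  vapply(seq_along(point), function(i) {
    sel <- which(genes$chrom == chrom[i])
    if (length(sel) == 0) return(NA_integer_)
    d <- abs(point[i] - genes$tss[sel])
    cand <- sel[d == min(d)]
    cand[order(genes$gene_id[cand])][1L]
  }, integer(1))
}

#' Simulate a TF peak set with known TSS linkage
#'
#' With probability `frac_tss_linked` a peak is attached to a random gene and
#' its summit placed at the TSS plus a strand-aware offset drawn from that
#' gene's class offset model; otherwise the summit falls uniformly in
#' gene-free space. Peak widths are uniform on `peak_width` with the summit
#' placed away from the edges. The ledger records, per peak, the linked gene
#' and drawn offset plus the realized nearest gene, signed distance and class
#' labels recomputed by the generator's own naive accounting.
#'
#' @param config a [sim_config()].
#' @param genes,gene_truth from [simulate_genes()].
#' @return List with `peaks` (narrowPeak-style table) and `ledger`
#'   (`data.frame`, one row per peak).
#' @export
simulate_peaks <- function(config, genes, gene_truth) {
  set.seed(config$seed + .SEED_PEAKS)
  n <- config$n_peaks
  chroms <- .chrom_names(config)
  cl_len <- stats::setNames(rep(config$chrom_length, config$n_chrom), chroms)
  class_of <- stats::setNames(gene_truth$class, gene_truth$gene_id)
  linked <- stats::runif(n) < config$frac_tss_linked & nrow(genes) > 0
  gene_idx <- ifelse(linked, sample.int(max(nrow(genes), 1L), n,
                                        replace = TRUE), NA_integer_)
  chrom <- character(n); summit <- integer(n); offset <- rep(NA_real_, n)
  # gene-free space per chromosome for background peaks
  freespace <- lapply(chroms, function(ch) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(g$span_start + 1L, g$span_end))
    gapr <- IRanges::setdiff(IRanges::IRanges(1L, as.integer(cl_len[ch])), ir)
    cbind(IRanges::start(gapr) - 1L, IRanges::end(gapr))
  })
  names(freespace) <- chroms
  for (i in seq_len(n)) {
    if (linked[i]) {
      g <- genes[gene_idx[i], ]
      cls <- class_of[g$gene_id]
      om <- if (cls == "expressed") config$offset_expressed
            else config$offset_silent
      d <- round(rtrunc_norm(1, om[["mean"]], om[["sd"]],
                             -config$offset_trunc, config$offset_trunc))
      s <- if (g$strand == "+") g$tss + d else g$tss - d
      s <- max(300L, min(as.integer(cl_len[g$chrom]) - 301L, as.integer(s)))
      chrom[i] <- g$chrom; summit[i] <- s
    } else {
      ch <- sample(chroms, 1L)
      fs <- freespace[[ch]]
      w <- fs[, 2] - fs[, 1]
      row <- sample.int(nrow(fs), 1L, prob = w)
      s <- fs[row, 1] + sample.int(max(w[row], 1L), 1L) - 1L
      s <- max(300L, min(as.integer(cl_len[ch]) - 301L, as.integer(s)))
      chrom[i] <- ch; summit[i] <- s
    }
  }
  width <- sample(seq(config$peak_width[1], config$peak_width[2]), n,
                  replace = TRUE)
  margin <- 20L
  summit_offset <- margin +
    vapply(width, function(w) sample.int(w - 2L * margin, 1L), integer(1)) - 1L
  start <- summit - summit_offset
  shift <- pmax(0L, -start)
  start <- start + shift
  summit_offset <- summit - start
  end <- start + width
  over <- pmax(0L, end - as.integer(cl_len[chrom]))
  start <- start - over; end <- end - over
  summit_offset <- summit - start
  peaks <- new_peak_set(sprintf("tf_%05d", seq_len(n)), chrom, start, end,
                        summit_offset, score = round(stats::runif(n, 5, 100)),
                        name = "tf_peaks")
  near <- .truth_nearest(chrom, summit, genes)
  assigned <- !is.na(near)
  ng <- genes[ifelse(assigned, near, 1L), , drop = FALSE]
  dist <- signed_tss_distance(summit, ng$tss, ng$strand)
  ledger <- data.frame(
    peak_id = peaks$peak_id, chrom = chrom, summit = summit,
    linked = linked,
    linked_gene = ifelse(linked, genes$gene_id[gene_idx], NA_character_),
    drawn_offset = rep(NA_integer_, n),  # realized offset, filled below
    nearest_gene = ifelse(assigned, ng$gene_id, "unassigned"),
    true_distance = ifelse(assigned, dist, NA_integer_),
    expr_class = ifelse(assigned,
                        unname(class_of[ng$gene_id]), "unknown"),
    proximity = ifelse(assigned, proximity_class(dist), NA_character_),
    orientation = ifelse(assigned & abs(dist) <= 1000L,
                         ifelse(dist < 0, "upstream", "downstream"),
                         NA_character_),
    stringsAsFactors = FALSE)
  # realized offset relative to the linked gene (post-clamping truth)
  lg <- match(ledger$linked_gene, genes$gene_id)
  ledger$drawn_offset <- ifelse(
    linked,
    signed_tss_distance(summit, genes$tss[ifelse(is.na(lg), 1L, lg)],
                        genes$strand[ifelse(is.na(lg), 1L, lg)]),
    NA_integer_)
  list(peaks = peaks, ledger = ledger)
}

#' Plant IUPAC motif instances into summit windows
#'
#' For every `(pattern, class, rate)` rule, each peak of that class receives
#' a uniform-random instantiation of the pattern at a random position inside
#' its summit window with probability `rate`. Planted instances never
#' overwrite one another; conflicting or too-small windows are skipped and
#' counted. Classes `expressed`/`silent` follow the ledger's target-gene
#' class; `proximal`/`distal` follow `|true_distance|` vs 1 kb.
#'
#' @param genome named character vector (modified copy returned).
#' @param peaks peak table from [simulate_peaks()].
#' @param ledger its ledger.
#' @param config a [sim_config()].
#' @param width summit-window width, default 75.
#' @return List with `genome` (sequences with motifs planted), `planted`
#'   (`data.frame(peak_id, pattern, pos, instance)`), `n_skipped`.
#' @export
plant_motifs <- function(genome, peaks, ledger, config, width = 75L) {
  set.seed(config$seed + .SEED_MOTIFS)
  rules <- config$plant_rates
  lens <- vapply(genome, nchar, integer(1))
  win <- summit_region(peaks, width, chrom_lengths = lens)
  occupied <- lapply(genome, function(x) cbind(integer(0), integer(0)))
  planted <- list(); n_skipped <- 0L
  for (r in seq_len(nrow(rules))) {
    pat <- rules$pattern[r]
    k <- nchar(pat)
    pat_chars <- .check_iupac(pat)
    in_class <- switch(
      rules$class[r],
      expressed = ledger$expr_class == "expressed",
      silent = ledger$expr_class == "silent",
      proximal = !is.na(ledger$true_distance) &
        abs(ledger$true_distance) <= 1000L,
      distal = !is.na(ledger$true_distance) &
        abs(ledger$true_distance) > 1000L,
      stop("unknown plant class: ", rules$class[r]))
    todo <- which(in_class & stats::runif(nrow(ledger)) < rules$rate[r])
    for (i in todo) {
      lo <- win$start[i]; hi <- win$end[i]
      if (hi - lo < k) { n_skipped <- n_skipped + 1L; next }
      pos <- lo + sample.int(hi - lo - k + 1L, 1L) - 1L
      ch <- win$chrom[i]
      occ <- occupied[[ch]]
      if (nrow(occ) > 0 &&
          any(pos < occ[, 2] & pos + k > occ[, 1])) {
        n_skipped <- n_skipped + 1L; next
      }
      inst <- paste(vapply(pat_chars, function(code) {
        set <- setdiff(.iupac_sets[[code]], "N")
        set[sample.int(length(set), 1L)]
      }, character(1)), collapse = "")
      occupied[[ch]] <- rbind(occ, c(pos, pos + k))
      planted[[length(planted) + 1L]] <-
        data.frame(peak_id = win$peak_id[i], chrom = ch, pattern = pat,
                   pos = pos, instance = inst, stringsAsFactors = FALSE)
    }
  }
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(peak_id = character(), chrom = character(),
               pattern = character(), pos = integer(), instance = character(),
               stringsAsFactors = FALSE)
  # apply all edits in one pass per chromosome (a substr<- per plant would
  # copy the whole sequence each time)
  for (ch in unique(planted$chrom)) {
    chars <- strsplit(genome[[ch]], "")[[1]]
    sub <- planted[planted$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      k <- nchar(sub$instance[j])
      chars[(sub$pos[j] + 1L):(sub$pos[j] + k)] <-
        strsplit(sub$instance[j], "")[[1]]
    }
    genome[[ch]] <- paste(chars, collapse = "")
  }
  list(genome = genome, planted = planted, n_skipped = n_skipped)
}

#' Simulate external mark peak sets with known co-occupancy
#'
#' Each TF peak independently seeds a mark peak with probability `q`, its
#' summit jittered within `mark_jitter` bp; background mark peaks fall
#' uniformly at the configured per-Mb rate.
#'
#' @param config a [sim_config()].
#' @param tf_peaks the TF peak table.
#' @return List with `marks` (named list of peak tables) and `seeded` (named
#'   list of logical vectors: which TF peaks seeded a mark).
#' @export
simulate_marks <- function(config, tf_peaks) {
  set.seed(config$seed + .SEED_MARKS)
  chroms <- .chrom_names(config)
  total_mb <- config$n_chrom * config$chrom_length / 1e6
  pt <- reference_point(tf_peaks)
  out <- list(); seeded_out <- list()
  for (mk in names(config$marks)) {
    m <- config$marks[[mk]]
    seeded <- stats::runif(nrow(tf_peaks)) < m$q
    s_pos <- pt[seeded] +
      sample(seq(-config$mark_jitter, config$mark_jitter),
             sum(seeded), replace = TRUE)
    s_chrom <- tf_peaks$chrom[seeded]
    n_bg <- stats::rpois(1, m$background_per_mb * total_mb)
    b_chrom <- sample(chroms, n_bg, replace = TRUE)
    b_pos <- sample.int(config$chrom_length - 1000L, n_bg, replace = TRUE) +
      500L
    ch <- c(s_chrom, b_chrom); pos <- c(s_pos, b_pos)
    w <- sample(seq(config$peak_width[1], config$peak_width[2]),
                length(pos), replace = TRUE)
    start <- pmax(0L, as.integer(pos - w %/% 2L))
    end <- pmin(as.integer(config$chrom_length), start + w)
    out[[mk]] <- new_peak_set(sprintf("%s_%05d", mk, seq_along(pos)),
                              ch, start, end, name = mk)
    seeded_out[[mk]] <- seeded
  }
  list(marks = out, seeded = seeded_out)
}

#' Generate a full synthetic dataset, optionally writing it to disk
#'
#' Runs sequence, gene, expression, peak, motif-planting and mark generation
#' under one master seed, and (when `dir` is given) writes `genome.fa`,
#' `genes.tsv`, `expression.tsv`, `tf_peaks.narrowPeak`, one
#' `mark_<name>.narrowPeak` per mark, and `ledger.json`. Re-reading the files
#' through the package's readers reproduces the in-memory objects.
#'
#' @param config a [sim_config()].
#' @param dir output directory, or `NULL` for in-memory only.
#' @param sequence generate genome sequence and plant motifs (`TRUE` by
#'   default; turning it off speeds up annotation-only studies).
#' @return List: `genome`, `genes`, `gene_truth`, `expression`, `peaks`,
#'   `marks`, `ledger` (list of `peaks`, `planted`, `seeded`), `config`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL,
                             sequence = TRUE) {
  gg <- simulate_genes(config)
  expr <- simulate_expression(config, gg$gene_truth)
  pk <- simulate_peaks(config, gg$genes, gg$gene_truth)
  genome <- NULL; planted <- NULL
  if (sequence) {
    genome <- simulate_sequence(config)
    pm <- plant_motifs(genome, pk$peaks, pk$ledger, config)
    genome <- pm$genome
    planted <- pm$planted
  }
  mk <- simulate_marks(config, pk$peaks)
  ledger <- list(peaks = pk$ledger, planted = planted, seeded = mk$seeded)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (sequence) write_genome(genome, file.path(dir, "genome.fa"))
    write_gene_models(gg$genes, file.path(dir, "genes.tsv"))
    write_expression(expr, file.path(dir, "expression.tsv"))
    write_peaks(pk$peaks, file.path(dir, "tf_peaks.narrowPeak"),
                format = "narrowPeak")
    for (m in names(mk$marks))
      write_peaks(mk$marks[[m]], file.path(dir, paste0("mark_", m,
                                                       ".narrowPeak")),
                  format = "narrowPeak")
    jsonlite::write_json(ledger, file.path(dir, "ledger.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(genome = genome, genes = gg$genes, gene_truth = gg$gene_truth,
       expression = expr, peaks = pk$peaks, marks = mk$marks,
       ledger = ledger, config = config)
}
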