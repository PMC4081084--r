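#' peakscape: downstream analysis of transcription-factor ChIP-seq peaks
#'
#' Tools to annotate ChIP-seq peaks to their nearest genes, stratify them by
#' target-gene expression, profile TSS-distance distributions, census
#' core-promoter elements in summit windows, and measure co-occupancy with
#' external peak sets. A synthetic-data generator with a ground-truth ledger
#' makes every stage testable end to end.
#'
#' All genomic coordinates inside the package are 0-based half-open (BED
#' convention); 1-based formats (GTF, FASTA-relative positions in Biostrings)
#' are converted at the boundary.
#'
#' @keywords internal
"_PACKAGE"

# ---- gene models -----------------------------------------------------------

#' Build a strand-aware gene-model table
#'
#' The gene model is the reference frame for all distance calculations. The
#' transcription start site (TSS) of a plus-strand gene is its span start; for
#' a minus-strand gene it is the last base of the span (`span_end - 1`). The
#' transcription end site (TES) is the opposite terminus.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open gene spans.
#' @param strand character vector of `"+"` or `"-"`.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `strand`,
#'   `span_start`, `span_end`, `tss`, `tes`.
#' @examples
#' gene_models("g1", "chr1", 100L, 200L, "+")$tss  # 100
#' gene_models("g2", "chr1", 100L, 200L, "-")$tss  # 199
#' @export
gene_models <- function(gene_id, chrom, start, end, strand) {
  gene_id <- as.character(gene_id)
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  strand <- as.character(strand)
  n <- length(gene_id)
  chrom <- rep_len(chrom, n)
  strand <- rep_len(strand, n)
  stopifnot(length(start) == n, length(end) == n)
  bad <- !strand %in% c("+", "-")
  if (any(bad))
    stop("unknown strand symbol: ", paste(unique(strand[bad]), collapse = ", "))
  if (any(start >= end))
    stop("gene span_start must be < span_end (gene ",
         gene_id[which(start >= end)[1]], ")")
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  tss <- ifelse(strand == "+", start, end - 1L)
  tes <- ifelse(strand == "+", end - 1L, start)
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             span_start = start, span_end = end,
             tss = as.integer(tss), tes = as.integer(tes),
             stringsAsFactors = FALSE)
}

#' Read gene models from GTF or a simple TSV dialect
#'
#' The TSV dialect has a header row and columns `gene_id`, `chrom`, `start`,
#' `end`, `strand` with 0-based half-open coordinates. GTF input (1-based
#' closed) is read through \pkg{rtracklayer} and converted; only records with
#' feature type `gene` are used (all records if none are typed `gene`).
#'
#' @param path path to the annotation file.
#' @param format `"tsv"` or `"gtf"`.
#' @return A gene-model `data.frame` as from [gene_models()].
#' @export
read_gene_models <- function(path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene model file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = c("character", "character",
                                            "integer", "integer", "character"),
                             stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(need %in% names(tab)))
      stop("gene TSV must have columns: ", paste(need, collapse = ", "))
    gene_models(tab$gene_id, tab$chrom, tab$start, tab$end, tab$strand)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene", na.rm = TRUE))
      gr <- gr[!is.na(gr$type) & gr$type == "gene"]
    ids <- S4Vectors::mcols(gr)$gene_id
    if (is.null(ids)) stop("GTF records carry no gene_id attribute")
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(strand == "*")) stop("unknown strand symbol: *")
    # GTF is 1-based closed; shift start to the 0-based half-open frame
    gene_models(ids, as.character(GenomicRanges::seqnames(gr)),
                GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr), strand)
  }
}

#' Write gene models to the package's TSV dialect
#'
#' @param genes gene-model `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = genes$span_start, end = genes$span_end,
                    strand = genes$strand, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- peaks -----------------------------------------------------------------

new_peak_set <- function(peak_id, chrom, start, end,
                         summit_offset = NA_integer_, score = NA_real_,
                         name = "peaks") {
  n <- length(start)
  df <- data.frame(peak_id = as.character(peak_id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   summit_offset = rep_len(as.integer(summit_offset), n),
                   score = rep_len(as.numeric(score), n),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(df$start >= df$end))
      stop("peak start must be < end (peak ",
           df$peak_id[which(df$start >= df$end)[1]], ")")
    so <- df$summit_offset
    bad <- !is.na(so) & (so < 0L | so >= df$end - df$start)
    if (any(bad))
      stop("summit_offset outside peak (peak ", df$peak_id[which(bad)[1]], ")")
    if (anyDuplicated(df$peak_id))
      stop("duplicate peak_id: ",
           paste(unique(df$peak_id[duplicated(df$peak_id)]), collapse = ", "))
  }
  attr(df, "set_name") <- name
  df
}

#' Read a peak set from BED or narrowPeak
#'
#' Coordinates are kept 0-based half-open as in BED. For narrowPeak the 10th
#' column is the summit offset from the peak start; the sentinel `-1` maps to
#' an absent summit (`NA`). Peaks whose name column is missing or `"."` get
#' auto-generated ids `peak_00001, ...`.
#'
#' @param path path to the peak file.
#' @param format `"bed"` (>= 3 columns) or `"narrowPeak"` (10 columns).
#' @param name label for the set (defaults to the file base name).
#' @return A peak `data.frame` with columns `peak_id`, `chrom`, `start`,
#'   `end`, `summit_offset`, `score`; the set label is in `attr(, "set_name")`.
#' @export
read_peaks <- function(path, format = c("bed", "narrowPeak"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("peak file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(track|browser|#)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  min_cols <- if (format == "bed") 3L else 10L
  if (length(lines) == 0)
    return(new_peak_set(character(), character(), integer(), integer(),
                        name = name))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < min_cols))
    stop("line ", lineno[which(ncols < min_cols)[1]], ": expected >= ",
         min_cols, " tab-separated columns")
  getcol <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, character(1))
  chrom <- getcol(1)
  start <- suppressWarnings(as.integer(getcol(2)))
  end <- suppressWarnings(as.integer(getcol(3)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop("line ", lineno[which(bad)[1]], ": non-integer coordinates")
  if (any(start >= end))
    stop("line ", lineno[which(start >= end)[1]], ": start >= end")
  nm <- getcol(4)
  auto <- sprintf("peak_%05d", seq_along(chrom))
  peak_id <- ifelse(is.na(nm) | nm == ".", auto, nm)
  explicit <- !(is.na(nm) | nm == ".")
  if (anyDuplicated(peak_id[explicit]))
    stop("duplicate peak_id: ", paste(
      unique(peak_id[explicit][duplicated(peak_id[explicit])]), collapse = ", "))
  score <- suppressWarnings(as.numeric(getcol(5)))
  summit <- rep(NA_integer_, length(chrom))
  if (format == "narrowPeak") {
    sm <- suppressWarnings(as.integer(getcol(10)))
    if (any(is.na(sm)))
      stop("line ", lineno[which(is.na(sm))[1]], ": non-integer summit column")
    summit <- ifelse(sm == -1L, NA_integer_, sm)
  }
  new_peak_set(peak_id, chrom, start, end, summit, score, name = name)
}

#' Write a peak set to BED or narrowPeak
#'
#' Inverse of [read_peaks()]: coordinates and summit offsets round-trip
#' exactly. Absent summits are written as the narrowPeak sentinel `-1`.
#'
#' @param peaks peak `data.frame`.
#' @param path output path.
#' @param format `"bed"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  score <- ifelse(is.na(peaks$score), 0, peaks$score)
  if (format == "bed") {
    out <- cbind(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                 score, ".")
  } else {
    summit <- ifelse(is.na(peaks$summit_offset), -1L, peaks$summit_offset)
    out <- cbind(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                 score, ".", 0, -1, -1, summit)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- expression ------------------------------------------------------------

#' Read an expression table (gene_id, rpkm)
#'
#' @param path TSV with a header row and columns `gene_id`, `rpkm`.
#' @return `data.frame` with one non-negative `rpkm` per `gene_id`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "rpkm") %in% names(tab)))
    stop("expression TSV must have columns gene_id, rpkm")
  tab$gene_id <- as.character(tab$gene_id)
  tab$rpkm <- as.numeric(tab$rpkm)
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id in expression table")
  if (any(is.na(tab$rpkm) | tab$rpkm < 0))
    stop("rpkm values must be non-negative")
  tab[, c("gene_id", "rpkm")]
}

#' @rdname read_expression
#' @param expr expression `data.frame`.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr[, c("gene_id", "rpkm")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- genome sequence -------------------------------------------------------

#' Read a genome FASTA into a named character vector
#'
#' Sequences are uppercased and restricted to the `A,C,G,T,N` alphabet.
#'
#' @param path FASTA file.
#' @return Named character vector, one uppercase sequence per chromosome.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  genome <- toupper(as.character(ss))
  names(genome) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad))
    stop("genome sequence contains characters outside A,C,G,T,N: ",
         names(genome)[which(bad)[1]])
  genome
}

#' @rdname read_genome
#' @param genome named character vector of sequences.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# ---- RPKM ------------------------------------------------------------------

#' Reads per kilobase of transcript per million mapped reads
#'
#' `rpkm = read_count * 1e9 / (gene_length * total_mapped)`. Used with a
#' cutoff of 1 to call genes expressed versus silent.
#'
#' @param read_count number of reads on the gene (vectorised).
#' @param gene_length gene length in bp, > 0.
#' @param total_mapped total mapped reads in the library, > 0.
#' @return Numeric RPKM values.
#' @examples
#' compute_rpkm(10, 1000, 1e7)  # exactly 1 at the cutoff
#' @export
compute_rpkm <- function(read_count, gene_length, total_mapped) {
  if (any(gene_length <= 0)) stop("gene_length must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  if (any(read_count < 0)) stop("read_count must be >= 0")
  read_count * 1e9 / (gene_length * total_mapped)
}
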