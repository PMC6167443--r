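#' Construct a gene model
#'
#' A strand-aware, exon-structured genomic feature. All coordinates are
#' 0-based, half-open (BED-like); GTF input/output converts at the boundary.
#'
#' @param id Unique feature identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 0-based half-open span; `start < end`.
#' @param biotype `"coding"` or `"lncRNA"`.
#' @param exons Two-column matrix of (start, end) intervals, sorted,
#'   non-overlapping, each within `[start, end)`. Defaults to a single exon
#'   spanning the whole gene.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(id, chrom, strand, start, end,
                       biotype = c("coding", "lncRNA"), exons = NULL) {
  biotype <- match.arg(biotype)
  start <- as.integer(start); end <- as.integer(end)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("gene_model: 'id' must be a non-empty string")
  if (!strand %in% c("+", "-"))
    stop("gene_model: strand must be '+' or '-' (got '", strand, "')")
  if (is.na(start) || is.na(end) || start >= end)
    stop("gene_model '", id, "': require start < end (got ", start, ", ", end, ")")
  if (is.null(exons)) exons <- matrix(c(start, end), ncol = 2L)
  exons <- matrix(as.integer(exons), ncol = 2L)
  if (nrow(exons) == 0L) stop("gene_model '", id, "': at least one exon required")
  if (any(exons[, 1L] >= exons[, 2L]))
    stop("gene_model '", id, "': exon start must be < exon end")
  if (is.unsorted(exons[, 1L], strictly = FALSE))
    stop("gene_model '", id, "': exons must be sorted by start")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("gene_model '", id, "': exons must be non-overlapping")
  if (exons[1L, 1L] < start || exons[nrow(exons), 2L] > end)
    stop("gene_model '", id, "': exons must lie within [start, end)")
  structure(list(id = id, chrom = as.character(chrom), strand = strand,
                 start = start, end = end, biotype = biotype, exons = exons),
            class = "gene_model")
}

#' Total exonic length of a gene model in bp
#' @param gene A [gene_model()].
#' @return Integer number of exonic bases.
#' @export
exonic_length <- function(gene) {
  sum(gene$exons[, 2L] - gene$exons[, 1L])
}

#' Construct a genome annotation
#'
#' @param genes List of [gene_model()] objects with unique ids.
#' @param chrom_lengths Named integer vector of chromosome lengths. If
#'   `NULL`, lengths are derived as the maximum gene end per chromosome.
#' @return An object of class `genome_annotation` with elements `genes`
#'   (named list) and `chrom_lengths`.
#' @export
genome_annotation <- function(genes, chrom_lengths = NULL) {
  ids <- vapply(genes, `[[`, character(1L), "id")
  if (anyDuplicated(ids))
    stop("genome_annotation: duplicate gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(genes) <- ids
  chroms <- vapply(genes, `[[`, character(1L), "chrom")
  ends <- vapply(genes, `[[`, integer(1L), "end")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(ends, chroms, max)
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
  } else {
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
    miss <- setdiff(unique(chroms), names(chrom_lengths))
    if (length(miss))
      stop("genome_annotation: no length for chromosome(s): ",
           paste(miss, collapse = ", "))
    over <- ends > chrom_lengths[chroms]
    if (any(over))
      stop("genome_annotation: gene(s) extend beyond chromosome length: ",
           paste(ids[over], collapse = ", "))
  }
  structure(list(genes = genes, chrom_lengths = chrom_lengths),
            class = "genome_annotation")
}

#' Look up a gene by id
#' @param annotation A [genome_annotation()].
#' @param id Gene identifier.
#' @return The [gene_model()]; error if absent.
#' @export
ann_gene <- function(annotation, id) {
  g <- annotation$genes[[id]]
  if (is.null(g)) stop("annotation: no gene with id '", id, "'")
  g
}

#' Flatten an annotation to a gene-level data frame
#' @param x A [genome_annotation()].
#' @param row.names,optional Ignored (S3 signature compatibility).
#' @param ... Ignored.
#' @return data.frame with columns id, chrom, strand, start, end, biotype.
#' @export
as.data.frame.genome_annotation <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  g <- x$genes
  data.frame(
    id = vapply(g, `[[`, character(1L), "id"),
    chrom = vapply(g, `[[`, character(1L), "chrom"),
    strand = vapply(g, `[[`, character(1L), "strand"),
    start = vapply(g, `[[`, integer(1L), "start"),
    end = vapply(g, `[[`, integer(1L), "end"),
    biotype = vapply(g, `[[`, character(1L), "biotype"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  df <- as.data.frame(x)
  cat("genome_annotation:", nrow(df), "genes (",
      sum(df$biotype == "coding"), "coding,",
      sum(df$biotype == "lncRNA"), "lncRNA ) on",
      length(x$chrom_lengths), "chromosome(s)\n")
  invisible(x)
}

# GRanges view of gene spans (optionally one biotype). Internal.
ann_gene_ranges <- function(annotation, biotype = NULL) {
  df <- as.data.frame(annotation)
  if (!is.null(biotype)) df <- df[df$biotype == biotype, , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = names(annotation$chrom_lengths)),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand, id = df$id
  )
}

# GRanges of exons for the given gene ids, with a gene_id column. Internal.
ann_exon_ranges <- function(annotation, ids) {
  gl <- annotation$genes[ids]
  n <- vapply(gl, function(g) nrow(g$exons), integer(1L))
  ex <- do.call(rbind, lapply(gl, `[[`, "exons"))
  GenomicRanges::GRanges(
    seqnames = factor(rep(vapply(gl, `[[`, character(1L), "chrom"), n),
                      levels = names(annotation$chrom_lengths)),
    ranges = IRanges::IRanges(start = ex[, 1L] + 1L, end = ex[, 2L]),
    strand = rep(vapply(gl, `[[`, character(1L), "strand"), n),
    gene_id = rep(ids, n)
  )
}

#' Construct a ChIP peak table
#'
#' Peaks are strandless intervals in 0-based half-open coordinates.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, `start < end`.
#' @param score Optional non-negative numeric vector.
#' @return data.frame of class `peak_set` with columns chrom, start, end,
#'   score.
#' @export
peak_set <- function(chrom = character(), start = integer(),
                     end = integer(), score = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.null(score)) score <- rep(NA_real_, length(start))
  if (length(start) && any(start >= end))
    stop("peak_set: require start < end for every peak")
  if (any(!is.na(score) & score < 0))
    stop("peak_set: scores must be non-negative")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   score = as.numeric(score), stringsAsFactors = FALSE)
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Construct a count matrix with sample conditions
#'
#' The container mirrors edgeR's `DGEList` idiom: a validated list holding
#' an integer feature-by-sample matrix plus per-sample condition labels and
#' optional per-feature lengths (needed for FPKM).
#'
#' @param counts Integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). All entries `>= 0`.
#' @param condition Named character vector mapping every sample id to a
#'   condition label (e.g. `naive`, `treg_wt`, `treg_kiko`).
#' @param feature_lengths Optional named numeric vector of feature lengths
#'   in bp.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition, feature_lengths = NULL) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count_matrix: 'counts' must be a matrix with row and column names")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("count_matrix: counts must be non-negative integers")
  storage.mode(counts) <- "double"  # avoid integer overflow in column sums
  miss <- setdiff(colnames(counts), names(condition))
  if (length(miss))
    stop("count_matrix: sample(s) without condition label: ",
         paste(miss, collapse = ", "))
  condition <- condition[colnames(counts)]
  if (!is.null(feature_lengths)) {
    feature_lengths <- feature_lengths[rownames(counts)]
    names(feature_lengths) <- rownames(counts)
  }
  structure(list(counts = counts, condition = condition,
                 feature_lengths = feature_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples; conditions:", paste(unique(x$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Samples belonging to a condition
#' @param cm A [count_matrix()].
#' @param condition Condition label.
#' @return Character vector of sample ids; error if the label is unknown.
#' @export
samples_of <- function(cm, condition) {
  if (!condition %in% cm$condition)
    stop("count_matrix: unknown condition '", condition, "'")
  names(cm$condition)[cm$condition == condition]
}

#' Construct a gapped pairwise alignment
#'
#' Columns where both sequences carry a gap are uninformative and are
#' dropped at construction.
#'
#' @param name_a,name_b Sequence names.
#' @param seq_a,seq_b Equal-length gapped sequences over `A,C,G,T,N,-`
#'   (case-insensitive).
#' @return An object of class `alignment_pair` with elements `name_a`,
#'   `name_b`, `a`, `b` (uppercase character vectors, one element per
#'   column) and `length`.
#' @export
alignment_pair <- function(name_a, name_b, seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b))
    stop("alignment_pair: sequences must have equal gapped length (",
         length(a), " vs ", length(b), ")")
  bad <- setdiff(unique(c(a, b)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("alignment_pair: invalid symbol(s): ", paste(bad, collapse = ", "))
  keep <- !(a == "-" & b == "-")
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("alignment_pair: alignment is empty after dropping gap-gap columns")
  structure(list(name_a = name_a, name_b = name_b, a = a, b = b,
                 length = length(a)),
            class = "alignment_pair")
}

# Per-column match indicator: identical non-gap, non-N symbols. Internal.
aln_matches <- function(aln) {
  aln$a == aln$b & aln$a != "-" & aln$a != "N"
}
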