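#' Read a GTF annotation
#'
#' Parses gene and exon records from a GTF2.2-style file (1-based inclusive
#' coordinates) into a [genome_annotation()] in the package's internal
#' 0-based half-open convention. The biotype is taken from the
#' `gene_biotype` attribute and defaults to `coding` when absent. Optional
#' `##chrom-length <chrom> <len>` header comments (written by
#' [write_gtf()]) populate chromosome lengths; otherwise lengths are
#' derived from gene extents.
#'
#' @param path Path to a GTF file.
#' @return A [genome_annotation()].
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  chrom_lengths <- NULL
  cl <- grep("^##chrom-length\\s", lines, value = TRUE)
  if (length(cl)) {
    parts <- strsplit(sub("^##chrom-length\\s+", "", cl), "\\s+")
    chrom_lengths <- stats::setNames(
      as.integer(vapply(parts, `[`, character(1L), 2L)),
      vapply(parts, `[`, character(1L), 1L))
  }
  gene_rows <- list(); exon_rows <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop("read_gtf: malformed line ", i, " (expected 9 tab-separated fields)")
    if (!f[3L] %in% c("gene", "exon")) next
    start1 <- suppressWarnings(as.integer(f[4L]))
    end1 <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start1) || is.na(end1))
      stop("read_gtf: malformed line ", i, " (non-integer coordinates)")
    if (end1 < start1)
      stop("read_gtf: line ", i, ": end (", end1, ") < start (", start1, ")")
    gid <- gtf_attr(f[9L], "gene_id")
    if (is.na(gid))
      stop("read_gtf: malformed line ", i, " (missing gene_id attribute)")
    rec <- list(chrom = f[1L], type = f[3L], start = start1 - 1L, end = end1,
                strand = f[7L], gene_id = gid,
                biotype = gtf_attr(f[9L], "gene_biotype"))
    if (f[3L] == "gene") gene_rows[[length(gene_rows) + 1L]] <- rec
    else exon_rows[[length(exon_rows) + 1L]] <- rec
  }
  exon_by_gene <- split(exon_rows,
                        vapply(exon_rows, `[[`, character(1L), "gene_id"))
  genes <- lapply(gene_rows, function(g) {
    ex <- exon_by_gene[[g$gene_id]]
    exons <- if (is.null(ex)) NULL else {
      m <- cbind(vapply(ex, `[[`, integer(1L), "start"),
                 vapply(ex, `[[`, integer(1L), "end"))
      m[order(m[, 1L]), , drop = FALSE]
    }
    bt <- if (is.na(g$biotype)) "coding" else g$biotype
    gene_model(g$gene_id, g$chrom, g$strand, g$start, g$end,
               biotype = bt, exons = exons)
  })
  orphan <- setdiff(names(exon_by_gene),
                    vapply(gene_rows, `[[`, character(1L), "gene_id"))
  if (length(orphan))
    stop("read_gtf: exon records without a gene record: ",
         paste(orphan, collapse = ", "))
  genome_annotation(genes, chrom_lengths = chrom_lengths)
}

# Extract one quoted attribute value from a GTF attribute field. Internal.
gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, '\\s+"([^"]*)"'), attrs))[[1L]]
  if (length(m) < 2L) NA_character_ else m[2L]
}

#' Write a GTF annotation
#'
#' Emits gene and exon records in 1-based inclusive coordinates, ordered by
#' (chrom, start, id), preceded by `##chrom-length` header comments so that
#' `read_gtf(write_gtf(a))` reproduces `a` exactly.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  df <- as.data.frame(annotation)
  out <- c("##format: gtf",
           sprintf("##chrom-length %s %d",
                   names(annotation$chrom_lengths),
                   as.integer(annotation$chrom_lengths)))
  if (nrow(df)) {
    df <- df[order(df$chrom, df$start, df$id), , drop = FALSE]
    for (id in df$id) {
      g <- annotation$genes[[id]]
      attrs <- sprintf('gene_id "%s"; gene_biotype "%s";', g$id, g$biotype)
      out <- c(out, paste(g$chrom, "lncsig", "gene", g$start + 1L, g$end, ".",
                          g$strand, ".", attrs, sep = "\t"))
      for (k in seq_len(nrow(g$exons)))
        out <- c(out, paste(g$chrom, "lncsig", "exon",
                            g$exons[k, 1L] + 1L, g$exons[k, 2L], ".",
                            g$strand, ".", attrs, sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a BED3+ peak file
#'
#' BED coordinates are 0-based half-open and are preserved verbatim. An
#' optional fifth column is read as the peak score.
#'
#' @param path Path to a BED file.
#' @return A [peak_set()] data frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) return(peak_set())
  f <- strsplit(lines, "[ \t]+")
  nf <- lengths(f)
  if (any(nf < 3L))
    stop("read_bed: line ", which(nf < 3L)[1L], ": fewer than 3 fields")
  co <- function(k) vapply(f, `[`, character(1L), k)
  s <- co(2L); e <- co(3L)
  bad <- !grepl("^[0-9]+$", s) | !grepl("^[0-9]+$", e)
  if (any(bad))
    stop("read_bed: line ", which(bad)[1L], ": non-integer coordinates")
  score <- rep(NA_real_, length(f))
  has5 <- nf >= 5L
  if (any(has5))
    score[has5] <- suppressWarnings(as.numeric(
      vapply(f[has5], `[`, character(1L), 5L)))
  peak_set(co(1L), as.integer(s), as.integer(e), score)
}

#' Write peaks as BED
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  if (!nrow(peaks)) { writeLines(character(), path); return(invisible(path)) }
  has_score <- !is.na(peaks$score)
  lines <- ifelse(has_score,
                  sprintf("%s\t%d\t%d\t.\t%g", peaks$chrom, peaks$start,
                          peaks$end, peaks$score),
                  sprintf("%s\t%d\t%d", peaks$chrom, peaks$start, peaks$end))
  writeLines(lines, path)
  invisible(path)
}

#' Read a count table with its condition (and optional length) side-cars
#'
#' The main table is a TSV with a header row of sample ids and feature ids
#' in the first column. `conditions_path` is a two-column TSV
#' (sample, condition); `lengths_path` an optional two-column TSV
#' (feature, length in bp).
#'
#' @param path Count TSV path.
#' @param conditions_path Sample-condition TSV path.
#' @param lengths_path Optional feature-length TSV path.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, conditions_path, lengths_path = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("read_counts: need a feature column plus >=1 sample")
  ids <- tab[[1L]]
  m <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(as.numeric(m))
  if (anyNA(num)) stop("read_counts: non-numeric count value")
  if (any(num < 0) || any(num != round(num)))
    stop("read_counts: counts must be non-negative integers")
  counts <- matrix(num, nrow = nrow(tab),
                   dimnames = list(ids, colnames(tab)[-1L]))
  cond <- utils::read.delim(conditions_path, header = TRUE, sep = "\t",
                            colClasses = "character")
  condition <- stats::setNames(cond[[2L]], cond[[1L]])
  lengths <- NULL
  if (!is.null(lengths_path)) {
    lt <- utils::read.delim(lengths_path, header = TRUE, sep = "\t")
    lengths <- stats::setNames(as.numeric(lt[[2L]]), as.character(lt[[1L]]))
  }
  count_matrix(counts, condition, feature_lengths = lengths)
}

#' Write a count matrix with its side-cars
#' @param cm A [count_matrix()].
#' @param path Count TSV path.
#' @param conditions_path Sample-condition TSV path.
#' @param lengths_path Optional feature-length TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, conditions_path, lengths_path = NULL) {
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(cm$condition), condition = cm$condition),
    conditions_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(lengths_path)) {
    if (is.null(cm$feature_lengths))
      stop("write_counts: no feature lengths to write")
    utils::write.table(
      data.frame(feature = names(cm$feature_lengths),
                 length = cm$feature_lengths),
      lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a pairwise alignment from aligned FASTA
#'
#' The file must contain exactly two records of equal gapped length.
#' Columns that are gaps in both sequences are dropped.
#'
#' @param path Aligned FASTA path.
#' @return An [alignment_pair()].
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) != 2L)
    stop("read_alignment_fasta: expected exactly 2 records, found ", length(ss))
  if (Biostrings::width(ss)[1L] != Biostrings::width(ss)[2L])
    stop("read_alignment_fasta: records have unequal aligned lengths (",
         Biostrings::width(ss)[1L], " vs ", Biostrings::width(ss)[2L], ")")
  alignment_pair(names(ss)[1L], names(ss)[2L],
                 as.character(ss[[1L]]), as.character(ss[[2L]]))
}

#' Write a pairwise alignment as aligned FASTA
#' @param aln An [alignment_pair()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  ss <- Biostrings::BStringSet(c(paste(aln$a, collapse = ""),
                                 paste(aln$b, collapse = "")))
  names(ss) <- c(aln$name_a, aln$name_b)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
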