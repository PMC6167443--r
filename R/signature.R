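#' Call the core up/down signature from differential-expression results
#'
#' @param results data.frame from [nb_wald_test()] covering the expressed
#'   universe.
#' @param expressed Character vector of expressed feature ids.
#' @param alpha Significance threshold (applied to `padj`, or to raw `p`
#'   when `use_raw_p = TRUE`).
#' @param use_raw_p Use unadjusted p-values for the cutoff.
#' @return An object of class `signature_set`: list with `up`, `down`,
#'   `nondiff` (character vectors, pairwise disjoint, union = expressed),
#'   `alpha`, `universe_size`.
#' @export
call_signature <- function(results, expressed, alpha = 0.05,
                           use_raw_p = FALSE) {
  miss <- setdiff(expressed, results$feature_id)
  if (length(miss))
    stop("call_signature: expressed feature(s) missing from results: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  r <- results[match(expressed, results$feature_id), , drop = FALSE]
  pv <- if (use_raw_p) r$p else r$padj
  up <- r$feature_id[pv < alpha & r$log2fc > 0]
  down <- r$feature_id[pv < alpha & r$log2fc < 0]
  sig <- structure(list(up = up, down = down,
                        nondiff = setdiff(expressed, c(up, down)),
                        alpha = alpha,
                        universe_size = length(expressed)),
                   class = "signature_set")
  validate_signature(sig)
  sig
}

# Assert the partition invariant of a signature_set. Internal.
validate_signature <- function(sig) {
  all_ids <- c(sig$up, sig$down, sig$nondiff)
  if (anyDuplicated(all_ids))
    stop("signature_set: up/down/nondiff must be pairwise disjoint")
  if (length(all_ids) != sig$universe_size)
    stop("signature_set: sets must partition the expressed universe")
  invisible(sig)
}

#' @export
print.signature_set <- function(x, ...) {
  s <- summarize_signature(x)
  cat(sprintf(
    "signature_set: %d up, %d down of %d expressed (%.1f%% differential)\n",
    s$n_up, s$n_down, s$n_expressed, s$pct_differential))
  invisible(x)
}

#' Summarize a signature set
#'
#' @param sig A `signature_set`.
#' @return List with `n_up`, `n_down`, `n_expressed` and
#'   `pct_differential` (percent of the expressed universe that is
#'   differential, one decimal).
#' @export
summarize_signature <- function(sig) {
  validate_signature(sig)
  if (sig$universe_size == 0L)
    stop("summarize_signature: empty expressed universe")
  n_up <- length(sig$up); n_down <- length(sig$down)
  pct <- 100 * (n_up + n_down) / sig$universe_size
  # report to one decimal, truncating: 245/1765 prints as 13.8%
  list(n_up = n_up, n_down = n_down, n_expressed = sig$universe_size,
       pct_differential = floor(pct * 10 + 1e-9) / 10)
}

#' Classify lncRNA position relative to protein-coding genes
#'
#' Span-level classification: `sense` if the lncRNA overlaps >= 1 bp of any
#' coding gene span on the same strand; `antisense` if it overlaps coding
#' genes only on the opposite strand; `lincRNA` if it overlaps none. When a
#' lncRNA overlaps coding genes on both strands via different genes, sense
#' wins (deterministic precedence). The `intronic` flag is true when the
#' lncRNA lies fully within some coding gene's span while overlapping none
#' of that gene's exons.
#'
#' @param annotation A [genome_annotation()] containing coding genes.
#' @param ids lncRNA ids to classify; default = all lncRNA in the
#'   annotation.
#' @return data.frame with columns feature_id, class, intronic.
#' @export
classify_positions <- function(annotation, ids = NULL) {
  df <- as.data.frame(annotation)
  if (is.null(ids)) ids <- df$id[df$biotype == "lncRNA"]
  bad <- ids[df$biotype[match(ids, df$id)] != "lncRNA"]
  if (length(bad))
    stop("classify_positions: not lncRNA: ", paste(bad, collapse = ", "))
  coding <- ann_gene_ranges(annotation, biotype = "coding")
  ldf <- df[match(ids, df$id), , drop = FALSE]
  lnc <- GenomicRanges::GRanges(
    factor(ldf$chrom, levels = names(annotation$chrom_lengths)),
    IRanges::IRanges(ldf$start + 1L, ldf$end), strand = ldf$strand)
  hits <- GenomicRanges::findOverlaps(lnc, coding, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  same <- as.character(GenomicRanges::strand(lnc))[qh] ==
    as.character(GenomicRanges::strand(coding))[sh]
  cls <- rep("lincRNA", length(ids))
  cls[unique(qh[!same])] <- "antisense"
  cls[unique(qh[same])] <- "sense"  # sense precedence over antisense
  # intronic: fully inside some hit gene's span, overlapping none of its exons
  within <- ldf$start[qh] >= (GenomicRanges::start(coding)[sh] - 1L) &
    ldf$end[qh] <= GenomicRanges::end(coding)[sh]
  intronic <- rep(FALSE, length(ids))
  cand <- which(within)
  if (length(cand)) {
    host_ids <- coding$id[sh[cand]]
    ex <- ann_exon_ranges(annotation, unique(host_ids))
    exov <- GenomicRanges::findOverlaps(lnc[qh[cand]], ex,
                                        ignore.strand = TRUE)
    clash <- ex$gene_id[S4Vectors::subjectHits(exov)] ==
      host_ids[S4Vectors::queryHits(exov)]
    hits_exon <- tapply(clash, S4Vectors::queryHits(exov), any)
    exonic <- rep(FALSE, length(cand))
    exonic[as.integer(names(hits_exon))] <- as.logical(hits_exon)
    ok <- tapply(!exonic, qh[cand], any)
    intronic[as.integer(names(ok))] <- as.logical(ok)
  }
  data.frame(feature_id = ids, class = cls, intronic = intronic,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify a single lncRNA
#' @param lnc A [gene_model()] with biotype `lncRNA` (or its id).
#' @param annotation A [genome_annotation()].
#' @return List with `class` and `intronic`.
#' @export
classify_position <- function(lnc, annotation) {
  id <- if (inherits(lnc, "gene_model")) lnc$id else lnc
  ann2 <- annotation
  if (inherits(lnc, "gene_model") && is.null(annotation$genes[[id]]))
    ann2 <- genome_annotation(c(annotation$genes, list(lnc)))
  if (ann2$genes[[id]]$biotype != "lncRNA")
    stop("classify_position: '", id, "' is not a lncRNA")
  res <- classify_positions(ann2, ids = id)
  list(class = res$class, intronic = res$intronic)
}

#' Positional-class enrichment of the core signature
#'
#' For each positional category and each core set (up, down), builds the
#' 2x2 table (core set vs nondiff) x (class == category vs not) and
#' reports proportions, the sample odds ratio, and the two-sided Fisher
#' exact p-value.
#'
#' @param sig A `signature_set`.
#' @param classes data.frame from [classify_positions()] covering the
#'   universe.
#' @return data.frame with one row per (set, class): n_set, prop_set,
#'   prop_nondiff, odds_ratio, p (NA when the set is empty).
#' @export
positional_enrichment <- function(sig, classes) {
  validate_signature(sig)
  univ <- c(sig$up, sig$down, sig$nondiff)
  miss <- setdiff(univ, classes$feature_id)
  if (length(miss))
    stop("positional_enrichment: unclassified feature(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  cls <- stats::setNames(classes$class, classes$feature_id)
  out <- list()
  for (set_name in c("up", "down")) {
    set_ids <- sig[[set_name]]
    for (cat in c("sense", "antisense", "lincRNA")) {
      a <- sum(cls[set_ids] == cat); b <- length(set_ids) - a
      c2 <- sum(cls[sig$nondiff] == cat); d <- length(sig$nondiff) - c2
      if (length(set_ids) == 0L) {
        or <- NA_real_; p <- NA_real_
      } else {
        ft <- fisher_exact_2x2(a, b, c2, d)
        or <- ft$odds_ratio; p <- ft$p
      }
      out[[length(out) + 1L]] <- data.frame(
        set = set_name, class = cat, n_set = a,
        prop_set = if (length(set_ids)) a / length(set_ids) else NA_real_,
        prop_nondiff = if (length(sig$nondiff)) c2 / length(sig$nondiff)
        else NA_real_,
        odds_ratio = or, p = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
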