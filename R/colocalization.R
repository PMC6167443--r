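#' Strand-aware promoter window of a gene
#'
#' For a `+` strand gene the window is `[start - upstream, start +
#' downstream)`; for a `-` strand gene `[end - downstream, end +
#' upstream)`. The window is clipped to `[0, chrom_len)`.
#'
#' @param gene A [gene_model()].
#' @param upstream,downstream Non-negative extents in bp.
#' @param chrom_len Chromosome length for clipping (default unbounded).
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
promoter_region <- function(gene, upstream = 2000, downstream = 500,
                            chrom_len = Inf) {
  if (upstream < 0 || downstream < 0)
    stop("promoter_region: extents must be non-negative")
  if (gene$strand == "+") {
    s <- gene$start - upstream; e <- gene$start + downstream
  } else {
    s <- gene$end - downstream; e <- gene$end + upstream
  }
  s <- max(0, s); e <- max(s, min(e, chrom_len))
  c(start = as.integer(s), end = as.integer(e))
}

#' Does a gene carry a peak in its promoter or gene body?
#'
#' True iff any peak on the same chromosome overlaps at least 1 bp of the
#' promoter window or the gene span. Peaks are strandless; the gene strand
#' is used only to orient the promoter.
#'
#' @param gene A [gene_model()].
#' @param peaks A [peak_set()].
#' @param upstream,downstream Promoter extents in bp.
#' @param chrom_len Chromosome length for promoter clipping.
#' @return Logical scalar.
#' @export
has_peak <- function(gene, peaks, upstream = 2000, downstream = 500,
                     chrom_len = Inf) {
  if (!nrow(peaks)) return(FALSE)
  prom <- promoter_region(gene, upstream, downstream, chrom_len)
  same <- peaks$chrom == gene$chrom
  ov <- function(s, e) peaks$start[same] < e & peaks$end[same] > s
  any(ov(prom[[1L]], prom[[2L]]) | ov(gene$start, gene$end))
}

#' Peak presence flags for a set of features
#'
#' @param annotation A [genome_annotation()].
#' @param ids Feature ids to flag.
#' @param peaks A [peak_set()].
#' @param upstream,downstream Promoter extents in bp.
#' @return data.frame with columns feature_id, has_peak, n_peaks, plus
#'   attributes `promoter_up` / `promoter_down` recording the extents.
#' @export
peak_flags <- function(annotation, ids, peaks, upstream = 2000,
                       downstream = 500) {
  flags <- logical(length(ids)); npk <- integer(length(ids))
  for (k in seq_along(ids)) {
    g <- ann_gene(annotation, ids[k])
    cl <- annotation$chrom_lengths[[g$chrom]]
    prom <- promoter_region(g, upstream, downstream, chrom_len = cl)
    same <- peaks$chrom == g$chrom
    hit <- (peaks$start[same] < prom[[2L]] & peaks$end[same] > prom[[1L]]) |
      (peaks$start[same] < g$end & peaks$end[same] > g$start)
    flags[k] <- any(hit); npk[k] <- sum(hit)
  }
  out <- data.frame(feature_id = ids, has_peak = flags, n_peaks = npk,
                    stringsAsFactors = FALSE)
  attr(out, "promoter_up") <- upstream
  attr(out, "promoter_down") <- downstream
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table. The odds ratio reported is the sample odds ratio
#' `(a d) / (b c)` (NA when undefined).
#'
#' @param a,b,c,d Non-negative integer cell counts, rows = groups, columns
#'   = outcome: table `rbind(c(a, b), c(c, d))`.
#' @param alternative `"two.sided"` (default) or `"greater"` (upper
#'   hypergeometric tail: first row enriched for the first outcome).
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("fisher_exact_2x2: cells must be non-negative integers")
  if (sum(cells) == 0) stop("fisher_exact_2x2: all-zero table")
  r1 <- a + b; c1 <- a + c; c2 <- b + d; n <- sum(cells)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, c1, c2, r1)
  p <- if (alternative == "greater") {
    min(1, sum(probs[support >= a]))
  } else {
    p_obs <- stats::dhyper(a, c1, c2, r1)
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * c)
  list(odds_ratio = or, p = p)
}

#' Peak-colocalization enrichment of the core signature
#'
#' Compares the peak frequency of the core set (up and down combined)
#' against the non-differential background with Fisher's exact test, and
#' reports the plain frequency ratio alongside. Per-direction rows are
#' included.
#'
#' @param sig A `signature_set`.
#' @param flags data.frame from [peak_flags()] covering the universe.
#' @return data.frame with one row per set (core, up, down): n, n_peak,
#'   freq, freq_nondiff, freq_ratio, odds_ratio, p.
#' @export
peak_enrichment <- function(sig, flags) {
  validate_signature(sig)
  if (!length(sig$nondiff))
    stop("peak_enrichment: empty non-differential background")
  univ <- c(sig$up, sig$down, sig$nondiff)
  miss <- setdiff(univ, flags$feature_id)
  if (length(miss))
    stop("peak_enrichment: unflagged feature(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  fl <- stats::setNames(flags$has_peak, flags$feature_id)
  nd_n <- length(sig$nondiff); nd_peak <- sum(fl[sig$nondiff])
  freq_nd <- nd_peak / nd_n
  one <- function(name, ids) {
    n <- length(ids); k <- sum(fl[ids])
    if (n == 0L)
      return(data.frame(set = name, n = 0L, n_peak = 0L, freq = NA_real_,
                        freq_nondiff = freq_nd, freq_ratio = NA_real_,
                        odds_ratio = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    ft <- fisher_exact_2x2(k, n - k, nd_peak, nd_n - nd_peak)
    data.frame(set = name, n = n, n_peak = k, freq = k / n,
               freq_nondiff = freq_nd,
               freq_ratio = if (freq_nd > 0) (k / n) / freq_nd else NA_real_,
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  }
  rbind(one("core", c(sig$up, sig$down)), one("up", sig$up),
        one("down", sig$down))
}
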