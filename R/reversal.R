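#' Reversal flags for the core signature in knockout cells
#'
#' Given knockout-vs-wildtype Treg log2 fold changes, a core up-regulated
#' feature is "reversed" when its KO log2FC is `<= -lfc_threshold`, a core
#' down-regulated feature when it is `>= +lfc_threshold`, and a
#' non-differential feature (the direction-free background rate) when
#' `|log2FC| >= lfc_threshold`.
#'
#' @param sig A `signature_set`.
#' @param ko_results data.frame with columns feature_id, log2fc (KO over
#'   WT) covering the universe.
#' @param lfc_threshold Non-negative threshold (default 0.5).
#' @return Named logical vector over the universe.
#' @export
reversal_flags <- function(sig, ko_results, lfc_threshold = 0.5) {
  validate_signature(sig)
  univ <- c(sig$up, sig$down, sig$nondiff)
  miss <- setdiff(univ, ko_results$feature_id)
  if (length(miss))
    stop("reversal_flags: feature(s) missing from ko_results: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  lfc <- stats::setNames(ko_results$log2fc, ko_results$feature_id)[univ]
  out <- logical(length(univ))
  names(out) <- univ
  out[sig$up] <- lfc[sig$up] <= -lfc_threshold
  out[sig$down] <- lfc[sig$down] >= lfc_threshold
  out[sig$nondiff] <- abs(lfc[sig$nondiff]) >= lfc_threshold
  out
}

#' Knockout reversal report
#'
#' Quantifies how much of the core signature collapses when the
#' transcription factor is lost: per-set counts, median KO log2FC and
#' reversed fraction; Fisher enrichment of reversal in the core versus the
#' non-differential background; and two-sided Mann-Whitney tests comparing
#' KO log2FC of the up set (and, sign-flipped, the down set) against the
#' background.
#'
#' The Fisher test is one-sided (enrichment): core reversal is flagged by
#' direction (up-set must fall, down-set must rise) while the background
#' rate is direction-free, so under a null knockout the background rate is
#' systematically about twice the core rate and a two-sided test would
#' flag that deficit as "significant".
#'
#' @inheritParams reversal_flags
#' @return List with `per_set` (data.frame: set, n, median_ko_lfc,
#'   fraction_reversed), `fisher` (odds_ratio, p) and `rank_test`
#'   (data.frame: set, U, p). Statistics are NA where a set is empty.
#' @export
reversal_report <- function(sig, ko_results, lfc_threshold = 0.5) {
  flags <- reversal_flags(sig, ko_results, lfc_threshold)
  lfc <- stats::setNames(ko_results$log2fc, ko_results$feature_id)
  sets <- list(up = sig$up, down = sig$down, nondiff = sig$nondiff)
  per_set <- do.call(rbind, lapply(names(sets), function(nm) {
    ids <- sets[[nm]]
    data.frame(set = nm, n = length(ids),
               median_ko_lfc = if (length(ids)) stats::median(lfc[ids])
               else NA_real_,
               fraction_reversed = if (length(ids)) mean(flags[ids])
               else NA_real_, stringsAsFactors = FALSE)
  }))
  core <- c(sig$up, sig$down)
  fisher <- if (length(core) && length(sig$nondiff)) {
    fisher_exact_2x2(sum(flags[core]), length(core) - sum(flags[core]),
                     sum(flags[sig$nondiff]),
                     length(sig$nondiff) - sum(flags[sig$nondiff]),
                     alternative = "greater")
  } else list(odds_ratio = NA_real_, p = NA_real_)
  rank_one <- function(nm, x) {
    if (!length(x) || !length(sig$nondiff))
      return(data.frame(set = nm, U = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    mw <- mann_whitney(x, lfc[sig$nondiff])
    data.frame(set = nm, U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  }
  rank_test <- rbind(rank_one("up", lfc[sig$up]),
                     rank_one("down", -lfc[sig$down]))
  list(per_set = per_set, fisher = fisher, rank_test = rank_test,
       lfc_threshold = lfc_threshold)
}

#' Mann-Whitney U test
#'
#' U with midrank ties. Exact two-sided p by enumeration of all group
#' assignments when `length(x) + length(y) <= 16`; otherwise a normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `U` (statistic for `x`), `p` and `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y))
    stop("mann_whitney: both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mid <- n1 * n2 / 2
  if (n <= 16L) {
    idx <- utils::combn(n, n1)
    usim <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(usim - mid) >= abs(u - mid) - 1e-9)
    list(U = u, p = p, method = "exact")
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = u, p = 1, method = "normal"))
    z <- (abs(u - mid) - 0.5) / sqrt(sigma2)
    list(U = u, p = min(1, 2 * stats::pnorm(-max(z, 0))), method = "normal")
  }
}

#' Cross-dataset signature concordance
#'
#' Compares log2 fold changes of the same contrast measured in two
#' datasets (e.g. thymic vs peripheral subsets) over the intersection of
#' their feature ids.
#'
#' @param lfc_a,lfc_b Named numeric vectors of log2 fold changes.
#' @return List with `n_shared`, `pearson_r`, `spearman_rho` and
#'   `sign_concordance` (fraction of shared features with matching log2FC
#'   sign, zeros excluded).
#' @export
cross_dataset_concordance <- function(lfc_a, lfc_b) {
  shared <- intersect(names(lfc_a), names(lfc_b))
  if (length(shared) < 3L)
    stop("cross_dataset_concordance: need >= 3 shared features, have ",
         length(shared))
  a <- lfc_a[shared]; b <- lfc_b[shared]
  nz <- a != 0 & b != 0
  list(n_shared = length(shared),
       pearson_r = stats::cor(a, b, method = "pearson"),
       spearman_rho = stats::cor(a, b, method = "spearman"),
       sign_concordance = if (any(nz)) mean(sign(a[nz]) == sign(b[nz]))
       else NA_real_)
}
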