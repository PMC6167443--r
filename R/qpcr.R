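#' Construct/validate a qPCR CT table
#'
#' @param df data.frame with columns sample, gene, replicate, ct. An NA
#'   ct means the replicate did not amplify (undetected); detected values
#'   must lie in (0, 45].
#' @return The validated data.frame with class `ct_table`.
#' @export
ct_table <- function(df) {
  need <- c("sample", "gene", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ct_table: missing column(s): ", paste(miss, collapse = ", "))
  det <- !is.na(df$ct)
  if (any(df$ct[det] <= 0 | df$ct[det] > 45))
    stop("ct_table: detected CT values must be in (0, 45]")
  class(df) <- unique(c("ct_table", class(df)))
  df
}

#' Read a CT table from TSV
#' @param path TSV with columns sample, gene, replicate, ct (NA =
#'   undetected).
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path) {
  ct_table(utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE))
}

# Mean detected CT for one (sample, gene); error when all undetected.
mean_ct <- function(ct, sample, gene) {
  v <- ct$ct[ct$sample == sample & ct$gene == gene]
  if (!length(v))
    stop("qpcr: gene '", gene, "' not measured in sample '", sample, "'")
  v <- v[!is.na(v)]
  if (!length(v))
    stop("qpcr: gene '", gene, "' undetected in all replicates of sample '",
         sample, "'")
  mean(v)
}

#' Reference-normalized delta-CT for one sample
#'
#' Replicates are averaged at the CT level (Livak procedure); multiple
#' reference genes are combined as the arithmetic mean of their per-gene
#' mean CTs, i.e. geometric-mean normalization on the expression scale.
#'
#' @param ct A [ct_table()].
#' @param sample Sample id.
#' @param target_gene Target gene id.
#' @param ref_genes Character vector of reference gene ids.
#' @return delta-CT (target mean CT minus mean reference CT).
#' @export
delta_ct <- function(ct, sample, target_gene, ref_genes) {
  if (!length(ref_genes)) stop("delta_ct: need >= 1 reference gene")
  tgt <- mean_ct(ct, sample, target_gene)
  refs <- vapply(ref_genes, function(g) mean_ct(ct, sample, g), numeric(1L))
  tgt - mean(refs)
}

#' Relative expression by the 2^-ddCt method
#'
#' @inheritParams delta_ct
#' @param calibrator Calibrator sample id (`fold = 1` when equal to
#'   `sample`).
#' @return List with `sample`, `gene`, `calibrator`, `delta_ct` and
#'   `fold = 2^-(dCT_sample - dCT_calibrator)`.
#' @export
ddct_fold <- function(ct, sample, calibrator, target_gene, ref_genes) {
  d_s <- delta_ct(ct, sample, target_gene, ref_genes)
  d_c <- delta_ct(ct, calibrator, target_gene, ref_genes)
  list(sample = sample, gene = target_gene, calibrator = calibrator,
       delta_ct = d_s, fold = 2^-(d_s - d_c))
}

#' Check for complete transcript absence in knockout samples
#'
#' A knockout sample counts as "absent" when every replicate of the gene
#' is undetected, or when its fold change versus the wildtype calibrator
#' falls below `fold_floor`. The calibrator delta-CT is the mean over the
#' wildtype samples' delta-CTs.
#'
#' @param ct A [ct_table()].
#' @param gene Target gene id.
#' @param ko_samples,wt_samples Sample id vectors.
#' @param ref_genes Reference gene ids.
#' @param fold_floor Fold threshold treated as absence (default 0.01).
#' @return List with `fold` (named vector over KO samples, NA when
#'   undetected), `absent` (named logical) and `all_absent`.
#' @export
knockout_check <- function(ct, gene, ko_samples, wt_samples, ref_genes,
                           fold_floor = 0.01) {
  d_wt <- vapply(wt_samples, function(s) delta_ct(ct, s, gene, ref_genes),
                 numeric(1L))
  d_cal <- mean(d_wt)
  fold <- stats::setNames(rep(NA_real_, length(ko_samples)), ko_samples)
  absent <- stats::setNames(logical(length(ko_samples)), ko_samples)
  for (s in ko_samples) {
    v <- ct$ct[ct$sample == s & ct$gene == gene]
    if (!length(v))
      stop("knockout_check: gene '", gene, "' not measured in sample '",
           s, "'")
    if (all(is.na(v))) {
      absent[s] <- TRUE
    } else {
      d <- delta_ct(ct, s, gene, ref_genes)
      fold[s] <- 2^-(d - d_cal)
      absent[s] <- fold[s] < fold_floor
    }
  }
  list(fold = fold, absent = absent, all_absent = all(absent))
}
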