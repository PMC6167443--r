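# Run expr under a local RNG stream, restoring global state. Internal.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a per-stage substream seed from a master seed. Adding a stage must
# not perturb other stages' streams, hence hashing on the stage name.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Simulation configuration for the synthetic Treg lncRNA world
#'
#' Defaults encode the structure the analysis assumes: a core signature of
#' 190 up- and 55 down-regulated lncRNA among ~2000 expressed lncRNA,
#' |log2FC| ~ N(2, 0.5^2), NB dispersion 0.1, 3 replicates per condition,
#' a doubled ChIP-peak rate at core loci (0.4 vs 0.2), and directional
#' reversal of 80% of core features when the transcription factor is lost.
#'
#' @param n_coding Number of protein-coding genes.
#' @param n_lnc Number of lncRNA genes.
#' @param n_up,n_down Planted core up/down lncRNA counts.
#' @param lfc_mean,lfc_sd Mean and sd of planted |log2 fold change|.
#' @param dispersion NB dispersion alpha (variance `mu + alpha mu^2`);
#'   `0` gives Poisson counts.
#' @param reps Replicates per condition (>= 2).
#' @param peak_rate_base Probability that a non-core lncRNA carries a
#'   planted peak.
#' @param peak_enrich Multiplier on `peak_rate_base` for core lncRNA.
#' @param background_peak_rate Expected background peaks per Mb of genome.
#' @param reversal_prob Probability that a core lncRNA reverts to baseline
#'   in knockout Tregs.
#' @param position_mix Named proportions (sense, antisense, lincRNA) for
#'   non-core lncRNA placement.
#' @param position_mix_core As `position_mix` but for core lncRNA; the
#'   default is lincRNA-heavy, mirroring the observed intergenic excess of
#'   the core signature.
#' @param seed Master seed; every generator derives its own substream.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_coding = 2000, n_lnc = 2000, n_up = 190, n_down = 55,
                       lfc_mean = 2.0, lfc_sd = 0.5, dispersion = 0.1,
                       reps = 3, peak_rate_base = 0.2, peak_enrich = 2.0,
                       background_peak_rate = 10, reversal_prob = 0.8,
                       position_mix = c(sense = 0.35, antisense = 0.25,
                                        lincRNA = 0.40),
                       position_mix_core = c(sense = 0.15, antisense = 0.15,
                                             lincRNA = 0.70),
                       seed = 1L) {
  cfg <- list(n_coding = as.integer(n_coding), n_lnc = as.integer(n_lnc),
              n_up = as.integer(n_up), n_down = as.integer(n_down),
              lfc_mean = lfc_mean, lfc_sd = lfc_sd, dispersion = dispersion,
              reps = as.integer(reps), peak_rate_base = peak_rate_base,
              peak_enrich = peak_enrich,
              background_peak_rate = background_peak_rate,
              reversal_prob = reversal_prob,
              position_mix = position_mix / sum(position_mix),
              position_mix_core = position_mix_core / sum(position_mix_core),
              seed = as.integer(seed))
  if (cfg$n_up + cfg$n_down > cfg$n_lnc)
    stop("sim_config: n_up + n_down must be <= n_lnc")
  for (p in c("peak_rate_base", "reversal_prob"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("sim_config: ", p, " must be in [0, 1]")
  if (cfg$dispersion < 0) stop("sim_config: dispersion must be >= 0")
  if (cfg$reps < 2L) stop("sim_config: reps must be >= 2")
  if (length(cfg$position_mix) != 3L || length(cfg$position_mix_core) != 3L)
    stop("sim_config: position mixes need 3 proportions (sense, antisense, lincRNA)")
  structure(cfg, class = "sim_config")
}

# Fixed geometry of synthetic coding genes: 3 x 1 kb exons over a 9 kb span,
# tiled every 15 kb, alternating over two chromosomes.
.sim_gene_pitch <- 15000L
.sim_gene_span <- 9000L

#' Simulate a genome annotation with planted lncRNA structure
#'
#' Coding genes are tiled with gaps on two synthetic chromosomes; each
#' lncRNA is placed so as to realize its assigned positional class exactly
#' (sense: overlapping a coding gene on the same strand; antisense: on the
#' opposite strand; lincRNA: overlapping no coding gene). When any
#' gene-overlapping lncRNA exists, at least one is placed fully inside an
#' intron of its host gene.
#'
#' @param config A [sim_config()].
#' @return List with `annotation` ([genome_annotation()]) and `truth`, a
#'   data.frame with one row per lncRNA: feature_id, core_direction
#'   (up/down/none), true_lfc, positional_class, intronic,
#'   has_planted_peak, reverts_in_ko.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, "annotation"), {
    nc <- config$n_coding; nl <- config$n_lnc
    chroms <- c("simchr1", "simchr2")
    genes <- vector("list", nc + nl)
    # coding genes
    chrom_of <- chroms[(seq_len(nc) - 1L) %% 2L + 1L]
    local_idx <- stats::ave(seq_len(nc), chrom_of, FUN = seq_along)
    gstart <- (local_idx - 1L) * .sim_gene_pitch
    gstrand <- sample(c("+", "-"), nc, replace = TRUE)
    for (i in seq_len(nc)) {
      s <- gstart[i]
      exons <- matrix(c(s, s + 1000L, s + 4000L, s + 5000L,
                        s + 8000L, s + 9000L), ncol = 2L, byrow = TRUE)
      genes[[i]] <- gene_model(sprintf("PC%04d", i), chrom_of[i], gstrand[i],
                               s, s + .sim_gene_span, biotype = "coding",
                               exons = exons)
    }
    # planted truth
    direction <- rep(c("up", "down", "none"),
                     c(config$n_up, config$n_down,
                       nl - config$n_up - config$n_down))
    lfc <- numeric(nl)
    lfc[direction == "up"] <- abs(stats::rnorm(config$n_up, config$lfc_mean,
                                               config$lfc_sd))
    lfc[direction == "down"] <- -abs(stats::rnorm(config$n_down,
                                                  config$lfc_mean,
                                                  config$lfc_sd))
    classes <- c("sense", "antisense", "lincRNA")
    pclass <- character(nl)
    is_core <- direction != "none"
    if (any(is_core))
      pclass[is_core] <- sample(classes, sum(is_core), replace = TRUE,
                                prob = config$position_mix_core)
    if (any(!is_core))
      pclass[!is_core] <- sample(classes, sum(!is_core), replace = TRUE,
                                 prob = config$position_mix)
    reverts <- is_core & stats::runif(nl) < config$reversal_prob
    rate <- ifelse(is_core, pmin(1, config$peak_rate_base * config$peak_enrich),
                   config$peak_rate_base)
    has_peak <- stats::runif(nl) < rate
    intronic <- rep(FALSE, nl)
    # lncRNA placement
    overlapping <- which(pclass != "lincRNA")
    if (length(overlapping)) {
      if (nc == 0L)
        stop("simulate_annotation: sense/antisense lncRNA require coding ",
             "genes; increase n_coding or set position mixes to all lincRNA")
      # unique hosts when possible: peaks planted for one lncRNA must not
      # leak into another's promoter-or-body window
      host <- sample(nc, length(overlapping),
                     replace = length(overlapping) > nc)
      intronic_one <- overlapping[1L]  # guaranteed intronic placement
      intronic[intronic_one] <- TRUE
    }
    lnc_ids <- sprintf("LNC%04d", seq_len(nl))
    # intergenic tiling region starts past the coding tile on each chromosome
    n_by_chrom <- table(factor(chrom_of, levels = chroms))
    linc_base <- stats::setNames(as.integer(n_by_chrom) * .sim_gene_pitch +
                                   10000L, chroms)
    linc_pitch <- 8000L
    linc_count <- c(0L, 0L); names(linc_count) <- chroms
    oi <- 0L
    for (j in seq_len(nl)) {
      len <- sample(500:3000, 1L)
      if (pclass[j] == "lincRNA") {
        ch <- chroms[(j - 1L) %% 2L + 1L]
        s <- linc_base[[ch]] + linc_count[[ch]] * linc_pitch
        linc_count[[ch]] <- linc_count[[ch]] + 1L
        st <- sample(c("+", "-"), 1L)
        genes[[nc + j]] <- gene_model(lnc_ids[j], ch, st, s, s + len,
                                      biotype = "lncRNA")
      } else {
        oi <- oi + 1L
        hg <- genes[[host[oi]]]
        st <- if (pclass[j] == "sense") hg$strand else
          setdiff(c("+", "-"), hg$strand)
        if (intronic[j]) {
          # fully inside intron 1: (exon1 end, exon2 start) = (+1000, +4000)
          ilen <- min(len, 2800L)
          s <- hg$start + 1000L + sample.int(3000L - ilen - 1L, 1L)
          genes[[nc + j]] <- gene_model(lnc_ids[j], hg$chrom, st, s, s + ilen,
                                        biotype = "lncRNA")
        } else {
          # fully inside the host span, so the peak window stays local
          s <- hg$start + sample.int(.sim_gene_span - len + 1L, 1L) - 1L
          genes[[nc + j]] <- gene_model(lnc_ids[j], hg$chrom, st, s, s + len,
                                        biotype = "lncRNA")
        }
      }
    }
    ann <- genome_annotation(genes)
    # pad chromosome ends so promoter windows never clip
    ann$chrom_lengths <- ann$chrom_lengths + 10000L
    truth <- data.frame(feature_id = lnc_ids, core_direction = direction,
                        true_lfc = lfc, positional_class = pclass,
                        intronic = intronic, has_planted_peak = has_peak,
                        reverts_in_ko = reverts, stringsAsFactors = FALSE)
    list(annotation = ann, truth = truth)
  })
}

#' Simulate ChIP peaks with planted colocalization structure
#'
#' Each lncRNA flagged `has_planted_peak` in the truth receives one peak
#' placed uniformly within its promoter window or gene body; background
#' peaks are added genome-wide at `background_peak_rate` per Mb.
#'
#' @param annotation A [genome_annotation()].
#' @param truth Truth data.frame from [simulate_annotation()].
#' @param config The [sim_config()] used to generate them.
#' @param promoter_up,promoter_down Promoter extent used for placement (bp).
#' @return A [peak_set()].
#' @export
simulate_peaks <- function(annotation, truth, config,
                           promoter_up = 2000, promoter_down = 500) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, "peaks"), {
    chrom <- character(); start <- integer(); end <- integer()
    for (id in truth$feature_id[truth$has_planted_peak]) {
      g <- ann_gene(annotation, id)
      prom <- promoter_region(g, promoter_up, promoter_down,
                              chrom_len = annotation$chrom_lengths[[g$chrom]])
      lo <- min(prom[1L], g$start); hi <- max(prom[2L], g$end)
      w <- sample(200:500, 1L)
      c0 <- lo + sample.int(max(1L, hi - lo), 1L) - 1L
      s <- max(0L, c0 - w %/% 2L)
      chrom <- c(chrom, g$chrom); start <- c(start, s); end <- c(end, s + w)
    }
    genome_mb <- sum(as.numeric(annotation$chrom_lengths)) / 1e6
    n_bg <- stats::rpois(1L, config$background_peak_rate * genome_mb)
    if (n_bg > 0L) {
      ch <- sample(names(annotation$chrom_lengths), n_bg, replace = TRUE,
                   prob = as.numeric(annotation$chrom_lengths))
      w <- sample(200:500, n_bg, replace = TRUE)
      s <- vapply(seq_len(n_bg), function(k)
        sample.int(annotation$chrom_lengths[[ch[k]]] - w[k], 1L) - 1L,
        integer(1L))
      chrom <- c(chrom, ch); start <- c(start, s); end <- c(end, s + w)
    }
    ps <- peak_set(chrom, start, end)
    ps[order(ps$chrom, ps$start), , drop = FALSE]
  })
}

#' Simulate an RNA-seq count matrix with planted differential expression
#'
#' Per-feature baseline means are drawn log-normally (meanlog 5, sdlog 1.5).
#' Counts are negative-binomial with the configured dispersion. Condition
#' means: `naive` = baseline; `treg_wt` = baseline * 2^true_lfc for core
#' lncRNA; `treg_kiko` = baseline for core features that revert in the
#' knockout, otherwise the `treg_wt` mean. Per-sample library-size factors
#' are drawn uniformly on the log scale in [0.5, 2].
#'
#' @param annotation A [genome_annotation()].
#' @param truth Truth data.frame from [simulate_annotation()].
#' @param config The [sim_config()].
#' @return A [count_matrix()] with conditions `naive`, `treg_wt`,
#'   `treg_kiko` (`reps` samples each) and exonic feature lengths.
#' @export
simulate_counts <- function(annotation, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, "counts"), {
    ids <- names(annotation$genes)
    nfeat <- length(ids)
    baseline <- stats::rlnorm(nfeat, meanlog = 5, sdlog = 1.5)
    names(baseline) <- ids
    lfc <- stats::setNames(rep(0, nfeat), ids)
    lfc[truth$feature_id] <- truth$true_lfc
    revert <- stats::setNames(rep(FALSE, nfeat), ids)
    revert[truth$feature_id] <- truth$reverts_in_ko
    mu <- cbind(naive = baseline,
                treg_wt = baseline * 2^lfc,
                treg_kiko = ifelse(revert, baseline, baseline * 2^lfc))
    reps <- config$reps
    conds <- rep(colnames(mu), each = reps)
    sample_ids <- paste(conds, rep(seq_len(reps), times = 3L), sep = "_")
    sf <- exp(stats::runif(length(sample_ids), log(0.5), log(2)))
    counts <- matrix(0, nrow = nfeat, ncol = length(sample_ids),
                     dimnames = list(ids, sample_ids))
    for (j in seq_along(sample_ids)) {
      m <- mu[, conds[j]] * sf[j]
      counts[, j] <- if (config$dispersion > 0)
        stats::rnbinom(nfeat, mu = m, size = 1 / config$dispersion)
      else stats::rpois(nfeat, m)
    }
    lengths <- vapply(annotation$genes, exonic_length, integer(1L))
    count_matrix(counts, stats::setNames(conds, sample_ids),
                 feature_lengths = lengths[ids])
  })
}

#' Simulate a pairwise alignment with planted conserved blocks
#'
#' Per-column match probability equals the block identity inside each
#' planted block and `background_identity` elsewhere; mismatch columns get
#' a uniformly chosen different base. No gaps are introduced.
#'
#' @param length Number of alignment columns.
#' @param blocks data.frame with columns start, end (0-based half-open
#'   column ranges) and identity in `[0, 1]`; blocks must not overlap.
#' @param background_identity Match probability outside blocks.
#' @param seed Integer seed.
#' @return An [alignment_pair()].
#' @export
simulate_alignment <- function(length, blocks = NULL,
                               background_identity = 0.4, seed = 1L) {
  if (is.null(blocks))
    blocks <- data.frame(start = integer(), end = integer(),
                         identity = numeric())
  if (nrow(blocks)) {
    if (any(blocks$start < 0) || any(blocks$end > length) ||
        any(blocks$start >= blocks$end))
      stop("simulate_alignment: blocks must satisfy 0 <= start < end <= length")
    if (any(blocks$identity < 0 | blocks$identity > 1))
      stop("simulate_alignment: block identities must be in [0, 1]")
    b <- blocks[order(blocks$start), , drop = FALSE]
    if (nrow(b) > 1L && any(b$start[-1L] < b$end[-nrow(b)]))
      stop("simulate_alignment: blocks must not overlap")
  }
  with_seed(seed, {
    p <- rep(background_identity, length)
    for (k in seq_len(nrow(blocks)))
      p[(blocks$start[k] + 1L):blocks$end[k]] <- blocks$identity[k]
    bases <- c("A", "C", "G", "T")
    a <- sample(bases, length, replace = TRUE)
    match <- stats::runif(length) < p
    b <- a
    n_mis <- sum(!match)
    if (n_mis) {
      shift <- sample.int(3L, n_mis, replace = TRUE)
      b[!match] <- bases[(match(a[!match], bases) - 1L + shift) %% 4L + 1L]
    }
    alignment_pair("seq_a", "seq_b", paste(a, collapse = ""),
                   paste(b, collapse = ""))
  })
}

#' Simulate a qPCR CT plate with known fold changes
#'
#' Target CT is `target_base_ct - log2(fold)` plus Gaussian noise; two
#' reference genes have constant CT plus noise. A `fold` of exactly 0
#' yields undetected (NA) target replicates, emulating a knockout with no
#' transcript. A calibrator sample with fold 1 is always included.
#'
#' @param true_folds Named numeric vector, sample id -> fold change
#'   relative to the calibrator. Values must be `>= 0`.
#' @param ref_ct CT of the reference genes.
#' @param noise_sd Gaussian CT noise sd.
#' @param seed Integer seed.
#' @param n_reps Technical replicates per well.
#' @param target_gene,ref_genes,calibrator Gene/sample naming.
#' @param target_base_ct Calibrator CT of the target gene.
#' @return A data.frame of class `ct_table` with columns sample, gene,
#'   replicate, ct (NA = undetected).
#' @export
simulate_qpcr <- function(true_folds, ref_ct = 20, noise_sd = 0.2, seed = 1L,
                          n_reps = 3L, target_gene = "target",
                          ref_genes = c("Ppia", "Rpl"),
                          calibrator = "calibrator", target_base_ct = 24) {
  if (any(true_folds < 0))
    stop("simulate_qpcr: fold changes must be >= 0 (0 = undetected)")
  if (is.null(names(true_folds)) || any(!nzchar(names(true_folds))))
    stop("simulate_qpcr: true_folds must be a named vector")
  folds <- c(stats::setNames(1, calibrator), true_folds)
  with_seed(seed, {
    rows <- list()
    for (s in names(folds)) {
      f <- folds[[s]]
      tct <- if (f == 0) rep(NA_real_, n_reps) else
        target_base_ct - log2(f) + stats::rnorm(n_reps, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, gene = target_gene, replicate = seq_len(n_reps),
        ct = tct, stringsAsFactors = FALSE)
      for (rg in ref_genes)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, gene = rg, replicate = seq_len(n_reps),
          ct = ref_ct + stats::rnorm(n_reps, 0, noise_sd),
          stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    class(tab) <- c("ct_table", "data.frame")
    tab
  })
}

#' Write a full simulated dataset to disk
#'
#' Emits the GTF/BED/TSV artifacts the readers in this package consume,
#' the truth table, and a JSON provenance record echoing the config.
#'
#' @param sim List with `annotation` and `truth` (from
#'   [simulate_annotation()]).
#' @param peaks A [peak_set()].
#' @param cm A [count_matrix()].
#' @param config The [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, peaks, cm, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(gtf = file.path(dir, "annotation.gtf"),
             bed = file.path(dir, "peaks.bed"),
             counts = file.path(dir, "counts.tsv"),
             conditions = file.path(dir, "conditions.tsv"),
             lengths = file.path(dir, "feature_lengths.tsv"),
             truth = file.path(dir, "truth.tsv"),
             provenance = file.path(dir, "provenance.json"))
  write_gtf(sim$annotation, paths[["gtf"]])
  write_bed(peaks, paths[["bed"]])
  write_counts(cm, paths[["counts"]], paths[["conditions"]],
               paths[["lengths"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(c(unclass(config), list(package = "lncsig")),
                       paths[["provenance"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
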