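# Documented defaults for the pipeline thresholds.
pipeline_defaults <- function() {
  list(alpha = 0.05, use_raw_p = FALSE, min_mean = 1, promoter_up = 2000,
       promoter_down = 500, lfc_threshold = 0.5, min_len = 100,
       min_id = 0.70, seed = 1L, out_dir = "lncsig_run")
}

#' Validate a pipeline configuration
#'
#' A configuration is a flat list (or a JSON file containing one) with the
#' threshold keys of `alpha`, `use_raw_p`, `min_mean`, `promoter_up`,
#' `promoter_down`, `lfc_threshold`, `min_len`, `min_id`, `seed`,
#' `out_dir`, plus an optional nested `simulation` block of [sim_config()]
#' arguments. Unknown keys are errors, not warnings: silent typos are the
#' main reproducibility hazard.
#'
#' @param config Path to a JSON file, or a list.
#' @return Validated config list of class `pipeline_config`, with defaults
#'   filled in and `simulation` instantiated as a [sim_config()].
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- pipeline_defaults()
  known <- c(names(defaults), "simulation")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("validate_config: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config),
                                                    "simulation")])
  if (cfg$alpha <= 0 || cfg$alpha > 1)
    stop("validate_config: alpha must be in (0, 1]")
  if (cfg$min_id < 0 || cfg$min_id > 1)
    stop("validate_config: min_id must be in [0, 1]")
  for (k in c("min_mean", "promoter_up", "promoter_down", "lfc_threshold",
              "min_len"))
    if (cfg[[k]] < 0) stop("validate_config: ", k, " must be non-negative")
  sim_args <- if (is.null(config$simulation)) list() else
    as.list(config$simulation)
  if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
  cfg$simulation <- do.call(sim_config, sim_args)
  structure(cfg, class = "pipeline_config")
}

#' Run the full signature-characterization pipeline on simulated data
#'
#' Stages, in order: simulate annotation/peaks/counts; size factors and
#' expressed-lncRNA filter; naive-vs-Treg differential expression and
#' signature call; positional classification and enrichment; ChIP-peak
#' colocalization enrichment; knockout-reversal analysis; cross-dataset
#' concordance against an independently re-simulated replicate dataset.
#' All stage artifacts are written under `config$out_dir`; re-running with
#' the same config and seed reproduces them byte-identically.
#'
#' @param config A `pipeline_config` from [validate_config()] (or a list /
#'   JSON path accepted by it).
#' @return An `analysis_report`: see [make_report()].
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (artifacts so far are under ", out, ")", call. = FALSE))
  }
  cfg_plain <- unclass(config)
  cfg_plain$simulation <- unclass(cfg_plain$simulation)
  logf("config: ", jsonlite::toJSON(cfg_plain, auto_unbox = TRUE))

  scfg <- config$simulation
  sim <- stage("simulate", simulate_annotation(scfg))
  peaks <- stage("simulate", simulate_peaks(sim$annotation, sim$truth, scfg,
                                            config$promoter_up,
                                            config$promoter_down))
  cm <- stage("simulate", simulate_counts(sim$annotation, sim$truth, scfg))
  write_simulation(sim, peaks, cm, scfg, file.path(out, "sim"))
  logf("simulated ", length(sim$annotation$genes), " genes, ",
       nrow(peaks), " peaks")

  sf <- stage("normalize", size_factors(cm))
  lnc_ids <- sim$truth$feature_id
  expressed <- stage("filter", intersect(
    filter_expressed(cm, sf, config$min_mean, condition = "treg_wt"),
    lnc_ids))
  disp <- stage("dispersion",
                estimate_dispersion(cm, sf, c("naive", "treg_wt")))
  de <- stage("de", nb_wald_test(cm, sf, disp, "naive", "treg_wt"))
  utils::write.table(de, file.path(out, "de_naive_vs_treg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sig <- stage("signature", call_signature(de, expressed, config$alpha,
                                           config$use_raw_p))
  sig_df <- data.frame(
    feature_id = c(sig$up, sig$down, sig$nondiff),
    set = rep(c("up", "down", "nondiff"),
              c(length(sig$up), length(sig$down), length(sig$nondiff))))
  utils::write.table(sig_df, file.path(out, "signature.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logf("signature: ", length(sig$up), " up, ", length(sig$down), " down of ",
       sig$universe_size, " expressed lncRNA")

  classes <- stage("classify", classify_positions(sim$annotation, expressed))
  utils::write.table(classes, file.path(out, "positional_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pos_enr <- stage("classify", positional_enrichment(sig, classes))

  flags <- stage("coloc", peak_flags(sim$annotation, expressed, peaks,
                                     config$promoter_up,
                                     config$promoter_down))
  utils::write.table(flags, file.path(out, "peak_flags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  coloc <- stage("coloc", peak_enrichment(sig, flags))

  disp_ko <- stage("reversal",
                   estimate_dispersion(cm, sf, c("treg_wt", "treg_kiko")))
  ko_de <- stage("reversal",
                 nb_wald_test(cm, sf, disp_ko, "treg_wt", "treg_kiko"))
  utils::write.table(ko_de, file.path(out, "de_ko_vs_wt.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  reversal <- stage("reversal",
                    reversal_report(sig, ko_de, config$lfc_threshold))

  # independent replicate dataset (same truth, fresh counts) for concordance
  scfg_b <- scfg
  scfg_b$seed <- stage_seed(scfg$seed, "replicate-dataset")
  cm_b <- stage("concordance", simulate_counts(sim$annotation, sim$truth,
                                               scfg_b))
  sf_b <- size_factors(cm_b)
  disp_b <- estimate_dispersion(cm_b, sf_b, c("naive", "treg_wt"))
  de_b <- nb_wald_test(cm_b, sf_b, disp_b, "naive", "treg_wt")
  concord <- stage("concordance", cross_dataset_concordance(
    stats::setNames(de$log2fc, de$feature_id)[expressed],
    stats::setNames(de_b$log2fc, de_b$feature_id)[expressed]))

  report <- make_report(config = config, signature = sig,
                        positional = list(classes = classes,
                                          enrichment = pos_enr),
                        colocalization = coloc, reversal = reversal,
                        concordance = concord)
  jsonlite::write_json(report_as_list(report),
                       file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  logf("report written to ", file.path(out, "report.json"))
  report
}

#' Aggregate stage outputs into an analysis report
#'
#' @param config The validated `pipeline_config`.
#' @param signature A `signature_set`.
#' @param positional List with `classes` and `enrichment`.
#' @param colocalization [peak_enrichment()] output.
#' @param reversal [reversal_report()] output.
#' @param concordance [cross_dataset_concordance()] output.
#' @return List of class `analysis_report` with a `provenance` block
#'   (seed, thresholds, package version).
#' @export
make_report <- function(config, signature, positional, colocalization,
                        reversal, concordance) {
  structure(list(
    signature_summary = summarize_signature(signature),
    positional = positional,
    colocalization = colocalization,
    reversal = reversal,
    concordance = concordance,
    provenance = list(
      seed = config$seed,
      thresholds = config[c("alpha", "use_raw_p", "min_mean", "promoter_up",
                            "promoter_down", "lfc_threshold", "min_len",
                            "min_id")],
      simulation = unclass(config$simulation),
      package_version = as.character(utils::packageVersion("lncsig")))
  ), class = "analysis_report")
}

# JSON-friendly view of a report. Internal.
report_as_list <- function(report) {
  r <- unclass(report)
  r$positional$classes <- NULL  # table already on disk; keep report compact
  r
}

#' @export
print.analysis_report <- function(x, ...) {
  s <- x$signature_summary
  cat("== lncRNA signature analysis ==\n")
  cat(sprintf("signature: %d up, %d down of %d expressed (%.1f%%)\n",
              s$n_up, s$n_down, s$n_expressed, s$pct_differential))
  core <- x$colocalization[x$colocalization$set == "core", ]
  cat(sprintf("peak colocalization: core %.2f vs nondiff %.2f (ratio %.2f, p = %.3g)\n",
              core$freq, core$freq_nondiff, core$freq_ratio, core$p))
  up <- x$reversal$per_set[x$reversal$per_set$set == "up", ]
  cat(sprintf("KO reversal: up-set fraction %.2f (Fisher p = %.3g)\n",
              up$fraction_reversed, x$reversal$fisher$p))
  cat(sprintf("concordance: r = %.3f, rho = %.3f, sign = %.2f (n = %d)\n",
              x$concordance$pearson_r, x$concordance$spearman_rho,
              x$concordance$sign_concordance, x$concordance$n_shared))
  invisible(x)
}
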