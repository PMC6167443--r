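test_that("planted positional classes are recovered exactly by construction", {
  all_linc <- c(sense = 0, antisense = 0, lincRNA = 1)
  cfg <- sim_config(n_coding = 30, n_lnc = 120, n_up = 10, n_down = 5,
                    position_mix = all_linc, position_mix_core = all_linc,
                    seed = 7)
  sim <- simulate_annotation(cfg)
  cls <- classify_positions(sim$annotation)
  expect_true(all(cls$class == "lincRNA"))
  # mixed default: every planted class called as planted
  cfg2 <- sim_config(n_coding = 60, n_lnc = 300, n_up = 30, n_down = 10,
                     seed = 8)
  sim2 <- simulate_annotation(cfg2)
  cls2 <- classify_positions(sim2$annotation)
  expect_equal(cls2$class[match(sim2$truth$feature_id, cls2$feature_id)],
               sim2$truth$positional_class)
  expect_true(any(sim2$truth$intronic))
  expect_true(all(cls2$intronic[match(sim2$truth$feature_id[sim2$truth$intronic],
                                      cls2$feature_id)]))
})

test_that("degenerate configs: no lncRNA, no coding hosts", {
  cfg <- sim_config(n_coding = 20, n_lnc = 0, n_up = 0, n_down = 0)
  sim <- simulate_annotation(cfg)
  expect_equal(nrow(sim$truth), 0L)
  expect_true(all(as.data.frame(sim$annotation)$biotype == "coding"))
  cfg2 <- sim_config(n_coding = 0, n_lnc = 10, n_up = 0, n_down = 0, seed = 2)
  expect_error(simulate_annotation(cfg2), "n_coding|lincRNA")
})

test_that("empirical class mix tracks position_mix within 3 points", {
  mix <- c(sense = 0.35, antisense = 0.25, lincRNA = 0.40)
  props <- matrix(0, 10, 3, dimnames = list(NULL, names(mix)))
  for (s in 1:10) {
    cfg <- sim_config(n_coding = 300, n_lnc = 2000, n_up = 0, n_down = 0,
                      position_mix = mix, seed = s)
    truth <- simulate_annotation(cfg)$truth
    props[s, ] <- table(factor(truth$positional_class,
                               levels = names(mix))) / 2000
  }
  expect_true(all(abs(colMeans(props) - mix) < 0.03))
})

test_that("simulate_peaks: rate-0 and rate-1 limits", {
  cfg0 <- sim_config(n_coding = 30, n_lnc = 60, n_up = 5, n_down = 5,
                     peak_rate_base = 0, peak_enrich = 1,
                     background_peak_rate = 0, seed = 3)
  sim0 <- simulate_annotation(cfg0)
  expect_false(any(sim0$truth$has_planted_peak))
  expect_equal(nrow(simulate_peaks(sim0$annotation, sim0$truth, cfg0)), 0L)

  cfg1 <- sim_config(n_coding = 30, n_lnc = 60, n_up = 5, n_down = 5,
                     peak_rate_base = 1, peak_enrich = 1,
                     background_peak_rate = 0, seed = 3)
  sim1 <- simulate_annotation(cfg1)
  pk <- simulate_peaks(sim1$annotation, sim1$truth, cfg1)
  fl <- peak_flags(sim1$annotation, sim1$truth$feature_id, pk)
  expect_true(all(fl$has_peak))
})

test_that("simulate_counts: dimensions, conditions, zero-dispersion limit", {
  cfg <- sim_config(n_coding = 40, n_lnc = 100, n_up = 10, n_down = 5,
                    seed = 4)
  sim <- simulate_annotation(cfg)
  cm <- simulate_counts(sim$annotation, sim$truth, cfg)
  expect_equal(dim(cm$counts), c(140L, 9L))
  expect_equal(as.vector(table(cm$condition)[c("naive", "treg_kiko",
                                               "treg_wt")]), rep(3L, 3))
  expect_true(all(cm$counts >= 0) && all(cm$counts == round(cm$counts)))
  expect_equal(cm$feature_lengths[sim$truth$feature_id[1]],
               setNames(exonic_length(ann_gene(sim$annotation,
                                               sim$truth$feature_id[1])),
                        sim$truth$feature_id[1]))

  # dispersion -> 0 with lfc 1: treg mean ~ 2x naive mean per core-up
  # feature (core kept a small minority so median-of-ratios is unbiased)
  cfg0 <- sim_config(n_coding = 10, n_lnc = 200, n_up = 30, n_down = 0,
                     lfc_mean = 1, lfc_sd = 0, dispersion = 0, seed = 5)
  sim0 <- simulate_annotation(cfg0)
  cm0 <- simulate_counts(sim0$annotation, sim0$truth, cfg0)
  sf <- size_factors(cm0)
  y <- sweep(cm0$counts, 2, sf, "/")
  ups <- sim0$truth$feature_id[sim0$truth$core_direction == "up"]
  ratio <- rowMeans(y[ups, cm0$condition == "treg_wt"]) /
    rowMeans(y[ups, cm0$condition == "naive"])
  expect_equal(median(ratio), 2, tolerance = 0.1)
  # KO reverts to baseline for reverting features
  revs <- sim0$truth$feature_id[sim0$truth$reverts_in_ko]
  ratio_ko <- rowMeans(y[revs, cm0$condition == "treg_kiko"]) /
    rowMeans(y[revs, cm0$condition == "naive"])
  expect_equal(median(ratio_ko), 1, tolerance = 0.1)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(n_coding = 30, n_lnc = 80, n_up = 8, n_down = 4,
                    seed = 11)
  s1 <- simulate_annotation(cfg); s2 <- simulate_annotation(cfg)
  expect_identical(s1, s2)
  expect_identical(simulate_counts(s1$annotation, s1$truth, cfg),
                   simulate_counts(s2$annotation, s2$truth, cfg))
  expect_identical(simulate_peaks(s1$annotation, s1$truth, cfg),
                   simulate_peaks(s2$annotation, s2$truth, cfg))
  cfg2 <- sim_config(n_coding = 30, n_lnc = 80, n_up = 8, n_down = 4,
                     seed = 12)
  expect_false(identical(simulate_annotation(cfg2)$truth$true_lfc,
                         s1$truth$true_lfc))
  # generators do not disturb the global RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_annotation(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("simulate_alignment: planted blocks and clean backgrounds", {
  ident <- simulate_alignment(150, data.frame(start = 0, end = 150,
                                              identity = 1), seed = 1)
  expect_equal(ident$a, ident$b)
  expect_error(simulate_alignment(100, data.frame(start = c(0, 30),
                                                  end = c(50, 80),
                                                  identity = c(1, 1))),
               "overlap")
  # random background at 0.25 identity: no qualifying window
  hits <- vapply(1:20, function(s) {
    aln <- simulate_alignment(500, NULL, background_identity = 0.25,
                              seed = s)
    nrow(find_ecrs(aln, 100, 0.70))
  }, numeric(1))
  expect_true(all(hits == 0))
  # one strong block in weak background: exactly one region, overlapping it
  found <- vapply(1:20, function(s) {
    aln <- simulate_alignment(500, data.frame(start = 100, end = 250,
                                              identity = 0.9),
                              background_identity = 0.4, seed = 100 + s)
    r <- find_ecrs(aln, 100, 0.70)
    nrow(r) == 1 && r$start < 250 && r$end > 100
  }, logical(1))
  expect_true(all(found))
})

test_that("sim_config rejects out-of-range parameters", {
  expect_error(sim_config(n_lnc = 100, n_up = 90, n_down = 20), "n_up")
  expect_error(sim_config(peak_rate_base = 1.2), "peak_rate_base")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(reps = 1), "reps")
})
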