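fake_results <- function(ids, p = 1, lfc = 0) {
  data.frame(feature_id = ids,
             log2fc = rep_len(lfc, length(ids)),
             p = rep_len(p, length(ids)),
             padj = rep_len(p, length(ids)), stringsAsFactors = FALSE)
}

test_that("call_signature partitions the universe at the threshold", {
  ids <- sprintf("f%02d", 1:10)
  sig <- call_signature(fake_results(ids, p = 1), ids)
  expect_length(sig$up, 0)
  expect_length(sig$down, 0)
  expect_setequal(sig$nondiff, ids)

  r <- fake_results(ids, p = 1)
  r$padj[1] <- 0; r$log2fc[1] <- 2
  r$padj[2] <- 0.01; r$log2fc[2] <- -1
  sig2 <- call_signature(r, ids, alpha = 0.05)
  expect_equal(sig2$up, ids[1])
  expect_equal(sig2$down, ids[2])
  expect_equal(sort(c(sig2$up, sig2$down, sig2$nondiff)), sort(ids))
  expect_equal(sig2$universe_size, 10L)

  expect_error(call_signature(r[-1, ], ids), "missing")
  # raw-p mode uses p, not padj
  r2 <- fake_results(ids, p = 1); r2$p[3] <- 0.01; r2$log2fc[3] <- 1
  expect_equal(call_signature(r2, ids, use_raw_p = TRUE)$up, ids[3])
  expect_length(call_signature(r2, ids)$up, 0)
})

test_that("summarize_signature reports the headline percentage", {
  mk <- function(nu, nd, ne) structure(
    list(up = sprintf("u%d", seq_len(nu)), down = sprintf("d%d", seq_len(nd)),
         nondiff = sprintf("n%d", seq_len(ne - nu - nd)), alpha = 0.05,
         universe_size = ne), class = "signature_set")
  expect_equal(summarize_signature(mk(190, 55, 1765))$pct_differential, 13.8)
  expect_equal(summarize_signature(mk(0, 0, 100))$pct_differential, 0)
  expect_equal(summarize_signature(mk(50, 50, 100))$pct_differential, 100)
  empty <- structure(list(up = character(), down = character(),
                          nondiff = character(), alpha = 0.05,
                          universe_size = 0L), class = "signature_set")
  expect_error(summarize_signature(empty), "empty")
})

test_that("classify_position handles the defining geometries", {
  coding <- gene_model("pc", "chr1", "+", 100, 500, biotype = "coding")
  ann <- genome_annotation(list(coding))
  sense <- gene_model("l1", "chr1", "+", 200, 300, biotype = "lncRNA")
  anti <- gene_model("l2", "chr1", "-", 200, 300, biotype = "lncRNA")
  linc <- gene_model("l3", "chr1", "+", 600, 700, biotype = "lncRNA")
  expect_equal(classify_position(sense, ann)$class, "sense")
  expect_equal(classify_position(anti, ann)$class, "antisense")
  expect_equal(classify_position(linc, ann)$class, "lincRNA")
  expect_error(classify_position(gene_model("x", "chr1", "+", 1, 5,
                                            biotype = "coding"), ann),
               "not a lncRNA")
})

test_that("intronic flag: fully inside the span, outside all exons", {
  host <- gene_model("pc", "chr1", "+", 0, 1000, biotype = "coding",
                     exons = matrix(c(0, 100, 900, 1000), ncol = 2,
                                    byrow = TRUE))
  ann <- genome_annotation(list(host))
  intr <- gene_model("li", "chr1", "+", 200, 800, biotype = "lncRNA")
  res <- classify_position(intr, ann)
  expect_equal(res$class, "sense")
  expect_true(res$intronic)
  # touching an exon clears the flag
  exonic <- gene_model("le", "chr1", "-", 50, 800, biotype = "lncRNA")
  res2 <- classify_position(exonic, ann)
  expect_equal(res2$class, "antisense")
  expect_false(res2$intronic)
})

test_that("flipping the lncRNA strand swaps sense/antisense only", {
  set.seed(21)
  for (i in 1:30) {
    ann <- random_annotation(n_genes = 8)
    df <- as.data.frame(ann)
    lnc_ids <- df$id[df$biotype == "lncRNA"]
    if (!length(lnc_ids)) next
    cls <- classify_positions(ann, lnc_ids)
    flipped <- ann
    for (id in lnc_ids)
      flipped$genes[[id]]$strand <-
        setdiff(c("+", "-"), flipped$genes[[id]]$strand)
    cls2 <- classify_positions(flipped, lnc_ids)
    swap <- c(sense = "antisense", antisense = "sense", lincRNA = "lincRNA")
    # ties (overlap on both strands) keep sense under precedence; exclude them
    both <- mapply(function(id, cl) cl == "sense" &&
                     cls2$class[cls2$feature_id == id] == "sense",
                   lnc_ids, cls$class)
    expect_equal(cls2$class[!both], unname(swap[cls$class[!both]]))
  }
})

test_that("classification agrees with the per-base oracle", {
  set.seed(31)
  for (i in 1:200) {
    ann <- random_annotation(n_genes = sample(3:8, 1))
    df <- as.data.frame(ann)
    lnc_ids <- df$id[df$biotype == "lncRNA"]
    if (!length(lnc_ids)) next
    cls <- classify_positions(ann, lnc_ids)
    coding <- ann$genes[df$id[df$biotype == "coding"]]
    for (id in lnc_ids) {
      oc <- oracle_classify(ann$genes[[id]], coding)
      got <- cls[cls$feature_id == id, ]
      if (oc$class == "antisense" && got$class == "sense") next # tie: sense wins
      expect_equal(got$class, oc$class, info = paste("seed-case", i, id))
      expect_equal(got$intronic, oc$intronic, info = paste("case", i, id))
    }
  }
})

test_that("positional enrichment: null mix, concentrated mix, planted excess", {
  mk_sig <- function(up, down, nondiff) structure(
    list(up = up, down = down, nondiff = nondiff, alpha = 0.05,
         universe_size = length(c(up, down, nondiff))),
    class = "signature_set")
  # identical class mix in core and nondiff
  up <- sprintf("u%d", 1:20); nd <- sprintf("n%d", 1:100)
  classes <- data.frame(
    feature_id = c(up, nd),
    class = c(rep(c("sense", "lincRNA"), 10), rep(c("sense", "lincRNA"), 50)),
    intronic = FALSE)
  enr <- positional_enrichment(mk_sig(up, character(), nd), classes)
  lincrow <- enr[enr$set == "up" & enr$class == "lincRNA", ]
  expect_equal(lincrow$odds_ratio, 1)
  expect_gt(lincrow$p, 0.5)
  # fully concentrated: p equals the hypergeometric tail of that table
  classes2 <- data.frame(feature_id = c(up, nd),
                         class = c(rep("lincRNA", 20), rep("sense", 100)),
                         intronic = FALSE)
  enr2 <- positional_enrichment(mk_sig(up, character(), nd), classes2)
  p2 <- enr2$p[enr2$set == "up" & enr2$class == "lincRNA"]
  expect_equal(p2, oracle_fisher_p(20, 0, 0, 100), tolerance = 1e-12)
  # planted lincRNA excess in the core over 20 generator seeds
  sigp <- numeric(20); orp <- numeric(20)
  for (s in 1:20) {
    cfg <- sim_config(n_coding = 150, n_lnc = 600, n_up = 60, n_down = 20,
                      seed = s)
    sim <- simulate_annotation(cfg)
    cls <- classify_positions(sim$annotation)
    truth_sig <- mk_sig(
      sim$truth$feature_id[sim$truth$core_direction == "up"],
      sim$truth$feature_id[sim$truth$core_direction == "down"],
      sim$truth$feature_id[sim$truth$core_direction == "none"])
    enr3 <- positional_enrichment(truth_sig, cls)
    row <- enr3[enr3$set == "up" & enr3$class == "lincRNA", ]
    sigp[s] <- row$p; orp[s] <- row$odds_ratio
  }
  expect_true(all(orp > 1))
  expect_lt(median(sigp), 0.01)
})
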