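make_cm <- function(counts, conds = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("f%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  if (is.null(conds)) conds <- setNames(rep("a", ncol(counts)),
                                        colnames(counts))
  count_matrix(counts, conds)
}

test_that("size factors: closed forms and the brute-force oracle agree", {
  m <- matrix(c(10, 20, 5, 40, 80, 20), ncol = 2)  # sample2 = 4 x sample1
  expect_equal(unname(size_factors(make_cm(m))), c(0.5, 2.0))
  m2 <- matrix(rep(c(3, 9, 27), 3), ncol = 3)
  expect_equal(unname(size_factors(make_cm(m2))), c(1, 1, 1))
  set.seed(42)
  for (i in 1:10) {
    m3 <- matrix(rpois(200, 50), ncol = 4)
    dimnames(m3) <- list(sprintf("f%02d", 1:50), sprintf("s%d", 1:4))
    expect_equal(size_factors(make_cm(m3)), oracle_size_factors(m3))
  }
})

test_that("size factors: permutation invariance and scaling equivariance", {
  set.seed(7)
  m <- matrix(rpois(120, 30) + 1, ncol = 4,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%d", 1:4)))
  sf <- size_factors(make_cm(m))
  perm <- sample(nrow(m))
  expect_equal(size_factors(make_cm(m[perm, ])), sf)
  m2 <- m; m2[, 2] <- m2[, 2] * 3
  sf2 <- size_factors(make_cm(m2))
  # multiplying sample 2 by k multiplies its factor by k before rescaling
  expect_equal(sf2[2] / sf2[1], 3 * sf[2] / sf[1], tolerance = 1e-12)
})

test_that("size factors fall back to a positive-entry pseudo-reference", {
  m <- matrix(c(0, 10, 6, 5, 0, 12, 10, 20, 0), ncol = 3,
              dimnames = list(c("f1", "f2", "f3"), c("s1", "s2", "s3")))
  expect_warning(sf <- size_factors(make_cm(m)), "pseudo-reference")
  expect_true(all(sf > 0))
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
})

test_that("dispersion estimation: Poisson floor, NB recovery, constant rows", {
  conds <- setNames(rep(c("a", "b"), each = 3), sprintf("s%d", 1:6))
  set.seed(11)
  floors <- numeric(20)
  for (i in 1:20) {
    m <- matrix(rpois(600, 100), ncol = 6,
                dimnames = list(sprintf("f%03d", 1:100), names(conds)))
    cm <- make_cm(m, conds)
    a <- estimate_dispersion(cm, size_factors(cm), c("a", "b"),
                             moderate = FALSE)
    floors[i] <- mean(a <= 1e-8)
  }
  expect_gt(mean(floors), 0.4)  # roughly half the MoM estimates go negative

  mu <- exp(rnorm(200, 5, 1))
  meds <- replicate(20, {
    m <- sapply(1:6, function(j) rnbinom(200, mu = mu, size = 10))
    dimnames(m) <- list(sprintf("f%03d", 1:200), names(conds))
    cm <- make_cm(m, conds)
    median(estimate_dispersion(cm, size_factors(cm), c("a", "b"),
                               moderate = FALSE))
  })
  expect_gte(median(meds), 0.05)
  expect_lte(median(meds), 0.2)

  m <- matrix(50, nrow = 3, ncol = 6,
              dimnames = list(c("f1", "f2", "f3"), names(conds)))
  cm <- make_cm(m, conds)
  a <- estimate_dispersion(cm, setNames(rep(1, 6), names(conds)),
                           c("a", "b"), moderate = FALSE)
  expect_true(all(a == 1e-8))

  cm1 <- make_cm(m[, 1:3], setNames(c("a", "b", "b"), colnames(m)[1:3]))
  expect_error(estimate_dispersion(cm1, setNames(rep(1, 3),
                                                 colnames(m)[1:3]),
                                   c("a", "b")), "replication")
})

test_that("NB Wald test: symmetry and zero-dispersion limit", {
  conds <- setNames(rep(c("a", "b"), each = 3), sprintf("s%d", 1:6))
  m <- matrix(rep(c(40, 80, 120), 6), ncol = 6,
              dimnames = list(c("f1", "f2", "f3"), names(conds)))
  cm <- make_cm(m, conds)
  sf <- size_factors(cm)
  disp <- setNames(rep(0.05, 3), rownames(m))
  de <- nb_wald_test(cm, sf, disp, "a", "b")
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$p, rep(1, 3), tolerance = 1e-9)

  m2 <- cbind(matrix(rep(c(100, 400), 3), ncol = 3),
              matrix(rep(c(800, 3200), 3), ncol = 3))
  dimnames(m2) <- list(c("f1", "f2"), names(conds))
  cm2 <- make_cm(m2, conds)
  de2 <- nb_wald_test(cm2, setNames(rep(1, 6), names(conds)),
                      setNames(rep(1e-8, 2), c("f1", "f2")), "a", "b")
  expect_equal(de2$log2fc, rep(3, 2), tolerance = 0.01)
  expect_lt(max(de2$p), 1e-10)

  expect_error(nb_wald_test(cm, sf, disp[-1], "a", "b"), "dispersion")
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("FPKM closed forms and scaling identity", {
  m <- matrix(c(1000, 0), ncol = 1, dimnames = list(c("f1", "f2"), "s1"))
  out <- fpkm(m, feature_lengths = c(f1 = 2000, f2 = 500),
              totals = c(s1 = 1e7))
  expect_equal(out["f1", "s1"], 50)
  expect_equal(out["f2", "s1"], 0)
  out2 <- fpkm(m, feature_lengths = c(f1 = 2000, f2 = 500),
               totals = c(s1 = 2e7))
  expect_equal(out2, out / 2)
  expect_error(fpkm(m, feature_lengths = c(f1 = 2000), totals = c(s1 = 1e7)),
               "missing length")
})

test_that("expressed filter honors the threshold in the designated condition", {
  conds <- setNames(c("naive", "naive", "treg_wt", "treg_wt"),
                    sprintf("s%d", 1:4))
  m <- rbind(f_hi = c(0, 0, 10, 10), f_lo = c(50, 50, 0, 0),
             f_edge = c(1, 1, 1, 1), f_zero = c(0, 0, 0, 0))
  colnames(m) <- names(conds)
  cm <- make_cm(m, conds)
  sf <- setNames(rep(1, 4), names(conds))
  expect_setequal(filter_expressed(cm, sf, min_mean = 1),
                  c("f_hi", "f_edge"))
  expect_setequal(filter_expressed(cm, sf, min_mean = 0), rownames(m))
  expect_error(filter_expressed(cm, sf, condition = "nope"), "unknown")
})
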