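# Independent brute-force oracles used to pin down the fast implementations.
# Each is written from the definition, not from the package's code path.

# Median-of-ratios size factors, straight from the formula.
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1L, function(r) all(r > 0))
  ref <- apply(counts[keep, , drop = FALSE], 1L,
               function(r) prod(r)^(1 / length(r)))
  s <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts)))
    s[j] <- median(counts[keep, j] / ref)
  s <- s / prod(s)^(1 / length(s))
  setNames(s, colnames(counts))
}

# Per-base promoter-or-body peak overlap.
oracle_has_peak <- function(gene, peaks, upstream, downstream,
                            chrom_len = Inf) {
  if (gene$strand == "+") {
    ps <- gene$start - upstream; pe <- gene$start + downstream
  } else {
    ps <- gene$end - downstream; pe <- gene$end + upstream
  }
  ps <- max(0, ps); pe <- max(ps, min(pe, chrom_len))
  bases <- unique(c(seq_len(pe - ps) + ps - 1L,
                    seq_len(gene$end - gene$start) + gene$start - 1L))
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] != gene$chrom) next
    pb <- seq_len(peaks$end[i] - peaks$start[i]) + peaks$start[i] - 1L
    if (length(intersect(bases, pb))) return(TRUE)
  }
  FALSE
}

# Per-base positional classification of one lncRNA against coding genes.
oracle_classify <- function(lnc, coding) {
  lb <- seq.int(lnc$start, lnc$end - 1L)
  same <- FALSE; oppo <- FALSE; intronic <- FALSE
  for (g in coding) {
    if (g$chrom != lnc$chrom) next
    gb <- seq.int(g$start, g$end - 1L)
    if (!length(intersect(lb, gb))) next
    if (g$strand == lnc$strand) same <- TRUE else oppo <- TRUE
    if (all(lb %in% gb)) {
      eb <- unlist(lapply(seq_len(nrow(g$exons)), function(k)
        seq.int(g$exons[k, 1L], g$exons[k, 2L] - 1L)))
      if (!length(intersect(lb, eb))) intronic <- TRUE
    }
  }
  list(class = if (same) "sense" else if (oppo) "antisense" else "lincRNA",
       intronic = intronic)
}

# Fisher two-sided p by full enumeration over the fixed-margin support.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0L, c1 - r2):min(r1, c1)
  pr <- vapply(support, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1), numeric(1L))
  obs <- pr[match(a, support)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Mann-Whitney by subset enumeration; U counted pairwise.
oracle_mw <- function(x, y) {
  pool <- c(x, y); n1 <- length(x); n <- length(pool)
  u_of <- function(xs, ys)
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u <- u_of(x, y)
  mid <- n1 * length(y) / 2
  sets <- combn(n, n1)
  us <- apply(sets, 2L, function(ix) u_of(pool[ix], pool[-ix]))
  list(U = u, p = mean(abs(us - mid) >= abs(u - mid) - 1e-9))
}

# Conserved-region scan testing every window directly, then the same
# merge/trim semantics re-derived with plain loops.
oracle_ecrs <- function(aln, min_len, min_id) {
  a <- aln$a; b <- aln$b
  m <- as.integer(a == b & a != "-" & a != "N")
  n <- length(m)
  if (n < min_len) return(data.frame(start = integer(), end = integer()))
  covered <- logical(n)
  for (s in 0:(n - min_len)) {
    if (mean(m[(s + 1L):(s + min_len)]) > min_id)
      covered[(s + 1L):(s + min_len)] <- TRUE
  }
  out <- data.frame(start = integer(), end = integer(), length = integer(),
                    identity = numeric())
  i <- 1L
  while (i <= n) {
    if (!covered[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && covered[j + 1L]) j <- j + 1L
    s <- i - 1L; e <- j  # 0-based half-open
    idf <- function(s0, e0) mean(m[(s0 + 1L):e0])
    while (idf(s, e) <= min_id && (e - s) > min_len) {
      if (idf(s, s + min_len) < idf(e - min_len, e)) s <- s + 1L
      else e <- e - 1L
    }
    if ((e - s) > min_len && idf(s, e) > min_id)
      out <- rbind(out, data.frame(start = s, end = e, length = e - s,
                                   identity = idf(s, e)))
    i <- j + 1L
  }
  out
}

# Column-to-sequence coordinate mapping by explicit counting.
oracle_seq_coords <- function(region, aln, which) {
  chars <- aln[[which]]
  pos <- -1L; first <- NA_integer_; last <- NA_integer_
  count_before <- sum(chars[seq_len(region$start)] != "-")
  for (i in (region$start + 1L):region$end) {
    if (chars[i] != "-") {
      pos <- sum(chars[seq_len(i)] != "-") - 1L
      if (is.na(first)) first <- pos
      last <- pos
    }
  }
  if (is.na(first)) list(start = count_before, end = count_before,
                         empty = TRUE)
  else list(start = first, end = last + 1L, empty = FALSE)
}

# Random small annotation for round-trip and oracle sweeps.
random_annotation <- function(n_genes = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- lapply(seq_len(n_genes), function(i) {
    chrom <- sample(c("chrA", "chrB"), 1L)
    start <- sample.int(5000L, 1L) - 1L
    len <- sample(200:2000, 1L)
    n_ex <- sample(1:3, 1L)
    cuts <- sort(sample(seq_len(len - 1L), 2L * n_ex - 2L))
    bounds <- c(0L, cuts, len)
    exons <- cbind(start + bounds[seq(1L, 2L * n_ex - 1L, by = 2L)],
                   start + bounds[seq(2L, 2L * n_ex, by = 2L)])
    gene_model(sprintf("G%02d", i), chrom,
               sample(c("+", "-"), 1L), start, start + len,
               biotype = sample(c("coding", "lncRNA"), 1L), exons = exons)
  })
  genome_annotation(genes)
}

# Random peak set on the chromosomes of an annotation-sized toy genome.
random_peaks <- function(n = 10, max_pos = 8000L) {
  start <- sample.int(max_pos, n) - 1L
  width <- sample(50:400, n, replace = TRUE)
  peak_set(sample(c("chrA", "chrB"), n, replace = TRUE), start,
           start + width)
}
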