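#' Percent identity of an alignment window
#'
#' Identity = matching columns / window width. A match is an identical
#' non-gap, non-N symbol pair; gap-vs-base and anything involving N count
#' as mismatches. Gap-gap columns were already dropped when the alignment
#' was read, so every column in the window is informative.
#'
#' @param aln An [alignment_pair()].
#' @param start,end 0-based half-open column range.
#' @return Identity in `[0, 1]`.
#' @export
window_identity <- function(aln, start, end) {
  if (start < 0 || end > aln$length || start >= end)
    stop("window_identity: require 0 <= start < end <= alignment length")
  m <- aln_matches(aln)
  sum(m[(start + 1L):end]) / (end - start)
}

#' Find evolutionarily conserved regions (ECRs)
#'
#' Slides a window of exactly `min_len` columns, one column at a time, and
#' marks every column covered by at least one window whose identity
#' exceeds `min_id`. Marked columns are merged into maximal runs; runs of
#' length > `min_len` whose overall identity exceeds `min_id` are
#' reported. A run failing the identity condition is trimmed greedily from
#' its lower-identity end (comparing the identities of its two terminal
#' `min_len`-column windows; ties trim the right end) until it passes or
#' falls to `min_len` columns, in which case it is dropped.
#'
#' @param aln An [alignment_pair()].
#' @param min_len Window width; reported regions are strictly longer.
#' @param min_id Identity threshold; reported regions strictly exceed it.
#' @return data.frame with columns start, end (0-based half-open column
#'   coordinates), length, identity; regions are disjoint and sorted.
#' @export
find_ecrs <- function(aln, min_len = 100, min_id = 0.70) {
  empty <- data.frame(start = integer(), end = integer(),
                      length = integer(), identity = numeric())
  n <- aln$length
  if (n < min_len) {
    message("find_ecrs: alignment (", n, " columns) shorter than min_len (",
            min_len, "); no regions reported")
    return(empty)
  }
  m <- as.integer(aln_matches(aln))
  cs <- c(0L, cumsum(m))
  starts <- 0:(n - min_len)
  wid <- (cs[starts + min_len + 1L] - cs[starts + 1L]) / min_len
  good <- starts[wid > min_id]
  if (!length(good)) return(empty)
  covered <- logical(n)
  # mark [s, s + min_len) for each qualifying window via a difference array
  d <- integer(n + 1L)
  for (s in good) { d[s + 1L] <- d[s + 1L] + 1L; d[s + min_len + 1L] <-
    d[s + min_len + 1L] - 1L }
  covered <- cumsum(d[seq_len(n)]) > 0L
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  out <- list()
  for (k in which(runs$values)) {
    e <- ends[k]; s <- e - runs$lengths[k]  # 0-based half-open [s, e)
    ident <- function(s0, e0) (cs[e0 + 1L] - cs[s0 + 1L]) / (e0 - s0)
    while (ident(s, e) <= min_id && (e - s) > min_len) {
      id_left <- ident(s, s + min_len)
      id_right <- ident(e - min_len, e)
      if (id_left < id_right) s <- s + 1L else e <- e - 1L
    }
    if ((e - s) > min_len && ident(s, e) > min_id)
      out[[length(out) + 1L]] <- data.frame(start = s, end = e,
                                            length = e - s,
                                            identity = ident(s, e))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  stopifnot(all(res$length > min_len), all(res$identity > min_id),
            !is.unsorted(res$start),
            all(res$start[-1L] >= res$end[-nrow(res)] | nrow(res) == 1L))
  res
}

#' Map an alignment-column region to ungapped sequence coordinates
#'
#' @param region One row of the [find_ecrs()] output (or any list with
#'   `start` and `end` alignment-column positions).
#' @param aln The [alignment_pair()].
#' @param which `"a"` or `"b"`: which sequence's coordinates to report.
#' @return List with `start`, `end` (0-based half-open positions on the
#'   ungapped sequence) and `empty` (TRUE when the region is entirely
#'   gapped in the chosen sequence; boundaries falling on gaps shrink
#'   inward).
#' @export
ecr_to_sequence_coords <- function(region, aln, which = c("a", "b")) {
  which <- match.arg(which)
  s <- region$start; e <- region$end
  if (s < 0 || e > aln$length || s >= e)
    stop("ecr_to_sequence_coords: region outside the alignment")
  chars <- aln[[which]]
  nongap <- chars != "-"
  cols <- (s + 1L):e
  inside <- cols[nongap[cols]]
  before <- c(0L, cumsum(nongap))  # before[i + 1] = nongap count in cols 1..i
  if (!length(inside))
    return(list(start = before[s + 1L], end = before[s + 1L], empty = TRUE))
  list(start = before[inside[1L]], end = before[inside[length(inside)] + 1L],
       empty = FALSE)
}
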