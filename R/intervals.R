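# Low-level interval algebra on 0-based inclusive [start, end] intervals held
# as two-column numeric matrices. All coordinates are integer-valued doubles
# (exact to 2^53), which keeps flattened multi-Gbp genomes representable; the
# IRanges equivalents are limited to 32-bit integers. Correctness against an
# IRanges / literal bp-set oracle is asserted in the test suite.

iv <- function(start = numeric(0), end = numeric(0)) {
  m <- cbind(start = as.numeric(start), end = as.numeric(end))
  if (nrow(m) && any(m[, 2] < m[, 1])) stop_data("interval end < start")
  m
}

iv_empty <- function() iv()

# Union of intervals: sorted, disjoint, with abutting intervals
# ([a,b], [b+1,c]) merged into one.
iv_merge <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(iv_empty())
  o <- order(m[, 1], m[, 2])
  s <- m[o, 1]
  e <- m[o, 2]
  ce <- cummax(e)
  n <- length(s)
  new_grp <- c(TRUE, s[-1] > ce[-n] + 1)
  last <- c(new_grp[-1], TRUE)
  cbind(start = s[new_grp], end = ce[last])
}

iv_total_len <- function(m) {
  if (nrow(m) == 0) return(0)
  sum(m[, 2] - m[, 1] + 1)
}

# Total intersected bp between two MERGED interval sets.
iv_intersect_len <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  # for each interval in a, overlapping b indices lie in [lo, hi]
  lo <- findInterval(a[, 1] - 1, b[, 2]) + 1
  hi <- findInterval(a[, 2], b[, 1])
  n <- pmax(0, hi - lo + 1)
  tot <- sum(n)
  if (tot == 0) return(0)
  ai <- rep.int(seq_len(nrow(a)), n)
  bi <- sequence(n) + rep.int(lo - 1, n)
  sum(pmin(a[ai, 2], b[bi, 2]) - pmax(a[ai, 1], b[bi, 1]) + 1)
}

# Per-interval overlap (bp) of each row of `m` with a MERGED mask.
iv_overlap_each <- function(m, mask) {
  if (nrow(m) == 0) return(numeric(0))
  if (nrow(mask) == 0) return(numeric(nrow(m)))
  lo <- findInterval(m[, 1] - 1, mask[, 2]) + 1
  hi <- findInterval(m[, 2], mask[, 1])
  n <- pmax(0, hi - lo + 1)
  out <- numeric(nrow(m))
  keep <- n > 0
  if (!any(keep)) return(out)
  ai <- rep.int(seq_len(nrow(m)), n)
  bi <- sequence(n) + rep.int(lo - 1, n)
  ov <- pmin(m[ai, 2], mask[bi, 2]) - pmax(m[ai, 1], mask[bi, 1]) + 1
  agg <- rowsum(ov, group = ai)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

iv_validate_disjoint <- function(m, what = "intervals") {
  if (nrow(m) <= 1) return(invisible(TRUE))
  o <- order(m[, 1], m[, 2])
  s <- m[o, 1]
  e <- m[o, 2]
  if (any(s[-1] <= e[-length(e)])) {
    stop_data(what, " must be disjoint")
  }
  invisible(TRUE)
}
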