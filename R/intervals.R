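# Internal interval helpers. All coordinates are 0-based half-open [start, end);
# conversion to/from the 1-based inclusive on-disk convention happens only in
# the file readers/writers.

iv <- function(start = numeric(0), end = numeric(0)) {
  stopifnot(length(start) == length(end))
  m <- cbind(start = as.numeric(start), end = as.numeric(end))
  if (any(m[, "end"] < m[, "start"])) stop("interval end < start", call. = FALSE)
  m
}

iv_empty <- function() iv()

iv_sort <- function(x) {
  if (nrow(x) <= 1L) return(x)
  x[order(x[, "start"], x[, "end"]), , drop = FALSE]
}

iv_width <- function(x) sum(x[, "end"] - x[, "start"])

# union of b subtracted from each interval of a; result sorted, disjoint
iv_subtract <- function(a, b) {
  if (nrow(a) == 0L) return(iv_empty())
  if (nrow(b) == 0L) return(iv_sort(a))
  b <- iv_sort(b)
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    s <- a[i, "start"]; e <- a[i, "end"]
    cur <- s
    for (j in seq_len(nrow(b))) {
      bs <- b[j, "start"]; be <- b[j, "end"]
      if (be <= cur || bs >= e) next
      if (bs > cur) { out_s <- c(out_s, cur); out_e <- c(out_e, bs) }
      cur <- max(cur, be)
      if (cur >= e) break
    }
    if (cur < e) { out_s <- c(out_s, cur); out_e <- c(out_e, e) }
  }
  iv(out_s, out_e)
}

iv_clip <- function(x, lo = 0, hi = Inf) {
  if (nrow(x) == 0L) return(x)
  s <- pmax(x[, "start"], lo); e <- pmin(x[, "end"], hi)
  keep <- e > s
  iv(s[keep], e[keep])
}

# does the (possibly zero-length) query [qs, qe) intersect any interval of x?
# a zero-length anchor at point p intersects [a, b) iff a <= p < b.
iv_hits <- function(qs, qe, x) {
  if (nrow(x) == 0L) return(FALSE)
  if (qe == qs) any(x[, "start"] <= qs & qs < x[, "end"])
  else any(x[, "start"] < qe & qs < x[, "end"])
}

# non-overlap + sortedness check
iv_is_disjoint_sorted <- function(x) {
  if (nrow(x) <= 1L) return(TRUE)
  all(diff(x[, "start"]) >= 0) && all(x[-nrow(x), "end"] <= x[-1L, "start"])
}

# is every interval of a contained in the union of b?
iv_contained <- function(a, b) {
  nrow(iv_subtract(a, b)) == 0L
}
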