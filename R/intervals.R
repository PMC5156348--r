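#' Interval-set algebra on the half-open real line
#'
#' Behavioural state tracks are sets of half-open intervals `[start, end)` in
#' seconds since local midnight. An interval set is represented as a two-column
#' numeric matrix (`start`, `end`) with zero or more rows. These helpers
#' implement the exact set operations the effort metrics are defined by:
#' normalization (sort + merge), union, intersection, difference and total
#' duration. All operations are exact to double precision; no rasterization
#' is involved (tests compare against a 1-second rasterization oracle).
#'
#' @param start,end numeric vectors of equal length; `end > start` elementwise.
#' @return `intervals()` returns a normalized interval matrix.
#' @examples
#' iv <- intervals(c(0, 5), c(10, 20))   # merges to [0, 20)
#' iv_total(iv)
#' @export
intervals <- function(start = numeric(0), end = numeric(0)) {
  if (length(start) != length(end))
    stop("start and end must have equal length")
  m <- cbind(start = as.numeric(start), end = as.numeric(end))
  if (any(!is.finite(m)))
    stop("interval endpoints must be finite")
  if (any(m[, 2] <= m[, 1]))
    stop("invalid interval: end <= start")
  iv_normalize(m)
}

empty_intervals <- function() {
  cbind(start = numeric(0), end = numeric(0))
}

as_intervals <- function(m) {
  if (is.null(m) || NROW(m) == 0) return(empty_intervals())
  m <- as.matrix(m)
  colnames(m) <- c("start", "end")
  m
}

#' @describeIn intervals Sort by start and merge overlapping or touching
#'   intervals; union-preserving, output pairwise disjoint.
#' @param m an interval matrix.
#' @export
iv_normalize <- function(m) {
  m <- as_intervals(m)
  n <- nrow(m)
  if (n <= 1L) return(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out_s <- numeric(n); out_e <- numeric(n)
  k <- 1L; out_s[1] <- m[1, 1]; out_e[1] <- m[1, 2]
  for (i in 2:n) {
    if (m[i, 1] <= out_e[k]) {            # overlap or touching: merge
      if (m[i, 2] > out_e[k]) out_e[k] <- m[i, 2]
    } else {
      k <- k + 1L
      out_s[k] <- m[i, 1]; out_e[k] <- m[i, 2]
    }
  }
  cbind(start = out_s[seq_len(k)], end = out_e[seq_len(k)])
}

#' @describeIn intervals Union of two interval sets.
#' @param a,b interval matrices.
#' @export
iv_union <- function(a, b) {
  iv_normalize(rbind(as_intervals(a), as_intervals(b)))
}

#' @describeIn intervals Intersection of two interval sets (two-pointer sweep
#'   over normalized inputs).
#' @export
iv_intersect <- function(a, b) {
  a <- iv_normalize(a); b <- iv_normalize(b)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(empty_intervals())
  out_s <- numeric(na + nb); out_e <- numeric(na + nb); k <- 0L
  i <- 1L; j <- 1L
  while (i <= na && j <= nb) {
    lo <- max(a[i, 1], b[j, 1])
    hi <- min(a[i, 2], b[j, 2])
    if (hi > lo) {
      k <- k + 1L
      out_s[k] <- lo; out_e[k] <- hi
    }
    if (a[i, 2] <= b[j, 2]) i <- i + 1L else j <- j + 1L
  }
  cbind(start = out_s[seq_len(k)], end = out_e[seq_len(k)])
}

#' @describeIn intervals Complement of an interval set within `[lo, hi)`.
#' @param lo,hi bounds of the universe interval.
#' @export
iv_complement <- function(m, lo, hi) {
  stopifnot(hi > lo)
  m <- iv_intersect(iv_normalize(m), cbind(lo, hi))
  if (nrow(m) == 0L) return(cbind(start = lo, end = hi))
  s <- c(lo, m[, 2])
  e <- c(m[, 1], hi)
  keep <- e > s
  cbind(start = s[keep], end = e[keep])
}

#' @describeIn intervals Set difference `a \\ b`, restricted to the span of `a`.
#' @export
iv_diff <- function(a, b) {
  a <- iv_normalize(a)
  if (nrow(a) == 0L) return(a)
  b <- iv_normalize(b)
  if (nrow(b) == 0L) return(a)
  lo <- min(a[, 1]); hi <- max(a[, 2])
  iv_intersect(a, iv_complement(b, lo, hi))
}

#' @describeIn intervals Total duration (sum of lengths) of an interval set.
#' @export
iv_total <- function(m) {
  m <- as_intervals(m)
  if (nrow(m) == 0L) return(0)
  sum(m[, 2] - m[, 1])
}

iv_clip <- function(m, lo, hi) {
  iv_intersect(m, cbind(lo, hi))
}
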