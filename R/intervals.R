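#' Interval algebra on half-open real intervals
#'
#' All timelines in this package are sets of half-open intervals
#' `[start, end)` in seconds on a per-patient clock starting at 0, stored as
#' two-column numeric matrices (`start`, `end`). Half-open intervals make
#' union/intersection/difference measure-exact: adjacent intervals share no
#' time, and the total duration of a disjoint set is simply `sum(end - start)`.
#'
#' `iv()` builds and validates a set; `iv_normalize()` sorts and merges
#' overlapping or touching intervals; `iv_union()`, `iv_intersect()` and
#' `iv_setdiff()` are the set operations; `iv_length()` is total measure.
#'
#' @param start,end numeric vectors of equal length; `start <= end` elementwise.
#' @name intervals
NULL

#' @rdname intervals
#' @return `iv()`: a two-column matrix of class `iv` (possibly zero rows);
#'   zero-length intervals (`start == end`) are dropped.
#' @export
iv <- function(start = numeric(), end = numeric()) {
  if (length(start) != length(end)) stop("start and end must have equal length")
  if (any(!is.finite(start)) || any(!is.finite(end))) stop("intervals must be finite")
  if (any(end < start)) stop("interval end before start")
  keep <- end > start
  m <- cbind(start = as.numeric(start[keep]), end = as.numeric(end[keep]))
  class(m) <- c("iv", class(m))
  m
}

as_iv <- function(x) {
  if (inherits(x, "iv")) return(x)
  if (is.null(x) || length(x) == 0L) return(iv())
  x <- as.matrix(x)
  iv(x[, 1L], x[, 2L])
}

#' @rdname intervals
#' @param x an `iv` matrix.
#' @export
iv_normalize <- function(x) {
  x <- as_iv(x)
  n <- nrow(x)
  if (n <= 1L) return(x)
  o <- order(x[, 1L], x[, 2L])
  s <- x[o, 1L]; e <- x[o, 2L]
  # merge runs where the next start does not exceed the running max end
  cum_e <- cummax(e)
  new_run <- c(TRUE, s[-1L] > cum_e[-n])
  first <- which(new_run)
  last <- c(first[-1L] - 1L, n)
  iv(s[first], cum_e[last])
}

#' @rdname intervals
#' @param a,b `iv` matrices.
#' @export
iv_union <- function(a, b) iv_normalize(rbind(as_iv(a), as_iv(b)))

#' @rdname intervals
#' @export
iv_intersect <- function(a, b) {
  a <- iv_normalize(a); b <- iv_normalize(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv())
  # pairwise clip; both sides are small (tens to hundreds of intervals)
  i <- rep(seq_len(nrow(a)), each = nrow(b))
  j <- rep(seq_len(nrow(b)), times = nrow(a))
  s <- pmax(a[i, 1L], b[j, 1L])
  e <- pmin(a[i, 2L], b[j, 2L])
  keep <- e > s
  iv_normalize(iv(s[keep], e[keep]))
}

#' @rdname intervals
#' @export
iv_setdiff <- function(a, b) {
  a <- iv_normalize(a); b <- iv_normalize(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(a)
  lo <- min(a[, 1L], b[, 1L]) - 1
  hi <- max(a[, 2L], b[, 2L]) + 1
  iv_intersect(a, iv_complement(b, lo, hi))
}

#' @rdname intervals
#' @param lo,hi bounds of the spanning window for the complement.
#' @export
iv_complement <- function(x, lo, hi) {
  x <- iv_intersect(iv_normalize(x), iv(lo, hi))
  if (nrow(x) == 0L) return(iv(lo, hi))
  iv(c(lo, x[, 2L]), c(x[, 1L], hi))
}

#' @rdname intervals
#' @export
iv_length <- function(x) {
  x <- as_iv(x)
  if (nrow(x) == 0L) return(0)
  sum(x[, 2L] - x[, 1L])
}

#' @rdname intervals
#' @param shift seconds to add to every boundary.
#' @export
iv_shift <- function(x, shift) {
  x <- as_iv(x)
  if (nrow(x) > 0L) {
    x[, 1L] <- x[, 1L] + shift
    x[, 2L] <- x[, 2L] + shift
  }
  x
}

# TRUE where each interval in `a` overlaps some interval of normalized set `b`
# by more than `min_overlap` seconds
iv_overlaps_any <- function(a, b, min_overlap = 0) {
  a <- as_iv(a)
  b <- iv_normalize(b)
  if (nrow(a) == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  vapply(seq_len(nrow(a)), function(k) {
    ol <- pmin(a[k, 2L], b[, 2L]) - pmax(a[k, 1L], b[, 1L])
    any(ol > min_overlap)
  }, logical(1))
}
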