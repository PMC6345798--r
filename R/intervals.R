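#' Construct an interval set
#'
#' An `interval_set` is an ordered collection of non-overlapping half-open
#' intervals `[start, end)` on the time axis (seconds). It is the carrier for
#' sleep epochs, epoch thirds, substates and exclusion masks. A point `t`
#' belongs to an interval iff `start <= t < end`, which guarantees that
#' touching intervals never double-count a spike.
#'
#' @param start,end Numeric vectors of equal length; `start[i] < end[i]`.
#' @param label Optional single string naming the set (e.g. `"NREM"`, `"OFF"`).
#' @param merge If `TRUE` (default), overlapping or touching input intervals
#'   are merged; if `FALSE`, overlapping inputs are an error and touching
#'   intervals are kept distinct.
#' @return An object of class `interval_set`: a data.frame with columns
#'   `start`, `end`, sorted by `start`, with a `label` attribute.
#' @examples
#' iv <- interval_set(c(0, 5), c(2, 9))
#' iv_duration(iv)
#' @export
interval_set <- function(start = numeric(), end = numeric(), label = NULL,
                         merge = TRUE) {
  if (length(start) != length(end))
    stop("start and end must have equal length")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("interval bounds must be finite")
  if (any(start >= end))
    stop("every interval must satisfy start < end")
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  if (length(start) > 1L) {
    if (merge) {
      ns <- numeric(0); ne <- numeric(0)
      cs <- start[1L]; ce <- end[1L]
      for (i in seq_along(start)[-1L]) {
        if (start[i] <= ce) {          # overlap or touch: extend
          ce <- max(ce, end[i])
        } else {
          ns <- c(ns, cs); ne <- c(ne, ce)
          cs <- start[i]; ce <- end[i]
        }
      }
      start <- c(ns, cs); end <- c(ne, ce)
    } else {
      if (any(start[-1L] < end[-length(end)]))
        stop("overlapping intervals (merge = FALSE)")
    }
  }
  structure(
    data.frame(start = start, end = end),
    label = label,
    class = c("interval_set", "data.frame")
  )
}

#' @rdname interval_set
#' @param x Object to test or coerce.
#' @export
is_interval_set <- function(x) inherits(x, "interval_set")

#' @rdname interval_set
#' @export
as_interval_set <- function(x, label = NULL) {
  if (is_interval_set(x)) return(x)
  if (is.data.frame(x)) return(interval_set(x$start, x$end, label = label))
  if (is.numeric(x) && length(x) == 2L)
    return(interval_set(x[1L], x[2L], label = label))
  stop("cannot coerce to interval_set")
}

#' Total duration of an interval set
#'
#' @param x An `interval_set`.
#' @return Sum of `end - start` over all intervals, in seconds.
#' @export
iv_duration <- function(x) {
  x <- as_interval_set(x)
  sum(x$end - x$start)
}

#' Number of intervals
#' @param x An `interval_set`.
#' @export
iv_count <- function(x) nrow(as_interval_set(x))

#' Intersection of two interval sets
#'
#' Set-theoretic intersection under the half-open convention: `[0,10)` and
#' `[10,20)` do not intersect.
#'
#' @param a,b `interval_set` objects (or coercible).
#' @param label Optional label for the result.
#' @return An `interval_set` covering exactly the points in both `a` and `b`.
#' @export
interval_intersect <- function(a, b, label = NULL) {
  a <- as_interval_set(a); b <- as_interval_set(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(interval_set(label = label))
  rs <- numeric(0); re <- numeric(0)
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    s <- max(a$start[i], b$start[j])
    e <- min(a$end[i], b$end[j])
    if (s < e) { rs <- c(rs, s); re <- c(re, e) }
    if (a$end[i] <= b$end[j]) i <- i + 1L else j <- j + 1L
  }
  interval_set(rs, re, label = label)
}

#' Difference of two interval sets
#'
#' Removes from `a` every point covered by `b`. Conservation holds exactly:
#' `iv_duration(a) == iv_duration(a minus b) + iv_duration(a intersect b)`.
#'
#' @param a,b `interval_set` objects (or coercible).
#' @param label Optional label for the result.
#' @return An `interval_set` covering exactly `a \ b`.
#' @export
interval_subtract <- function(a, b, label = NULL) {
  a <- as_interval_set(a); b <- as_interval_set(b)
  if (nrow(a) == 0L) return(interval_set(label = label))
  if (nrow(b) == 0L) return(interval_set(a$start, a$end, label = label))
  rs <- numeric(0); re <- numeric(0)
  j <- 1L
  for (i in seq_len(nrow(a))) {
    cur <- a$start[i]; aend <- a$end[i]
    while (j <= nrow(b) && b$end[j] <= cur) j <- j + 1L
    k <- j
    while (k <= nrow(b) && b$start[k] < aend) {
      if (b$start[k] > cur) { rs <- c(rs, cur); re <- c(re, b$start[k]) }
      cur <- max(cur, b$end[k])
      if (cur >= aend) break
      k <- k + 1L
    }
    if (cur < aend) { rs <- c(rs, cur); re <- c(re, aend) }
  }
  interval_set(rs, re, label = label)
}

#' Union of two interval sets
#'
#' @param a,b `interval_set` objects (or coercible).
#' @param label Optional label for the result.
#' @return Merged `interval_set` covering the points of either input.
#' @export
interval_union <- function(a, b, label = NULL) {
  a <- as_interval_set(a); b <- as_interval_set(b)
  interval_set(c(a$start, b$start), c(a$end, b$end), label = label)
}

#' Membership test for points in an interval set
#'
#' @param t Numeric vector of time points.
#' @param x An `interval_set`.
#' @return Logical vector: `t[i]` lies in some `[start, end)` of `x`.
#' @export
iv_contains <- function(t, x) {
  x <- as_interval_set(x)
  if (nrow(x) == 0L || length(t) == 0L) return(rep(FALSE, length(t)))
  idx <- findInterval(t, x$start)   # number of starts <= t
  idx > 0L & t < x$end[pmax(idx, 1L)]
}

#' Count spikes falling inside a mask
#'
#' Each spike time `t` is counted iff `start <= t < end` for some interval of
#' the mask. The occupied duration is the mask's total duration, so
#' `count / duration` is the mask-restricted mean firing rate.
#'
#' @param spike_times Sorted (ascending) numeric vector of spike times, s.
#' @param mask An `interval_set`.
#' @return List with `count` (integer) and `duration_s` (numeric).
#' @export
count_spikes_in <- function(spike_times, mask) {
  mask <- as_interval_set(mask)
  if (nrow(mask) == 0L)
    return(list(count = 0L, duration_s = 0))
  if (is.unsorted(spike_times)) spike_times <- sort(spike_times)
  # spikes with t < z, via half-open search on the sorted spike vector
  n_below <- function(z) findInterval(z, spike_times, left.open = TRUE)
  cnt <- sum(n_below(mask$end) - n_below(mask$start))
  list(count = as.integer(cnt), duration_s = iv_duration(mask))
}

#' @export
print.interval_set <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<interval_set%s: %d interval(s), %.3f s total>\n",
              if (is.null(lab)) "" else paste0(" '", lab, "'"),
              nrow(x), iv_duration(x)))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
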