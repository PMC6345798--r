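#' Hypnogram of scored sleep/wake states
#'
#' A hypnogram is an ordered table of labeled, mutually non-overlapping,
#' half-open intervals with states from `WAKE`, `NREM`, `REM` and (optionally)
#' `MA` for externally scored microarousals. Scoring itself is an input; this
#' package only consumes the interval table.
#'
#' @param state Character vector of state labels.
#' @param start,end Numeric interval bounds, seconds, half-open `[start, end)`.
#' @param session_start,session_end Session bounds; default to the extremes of
#'   the supplied intervals.
#' @param merge_touching Merge touching/overlapping same-state rows into one
#'   interval (default `TRUE`). Cross-state overlap is always an error.
#' @return An object of class `hypnogram`: data.frame with columns `state`,
#'   `start`, `end`, sorted by `start`, plus `session_start`/`session_end`
#'   attributes.
#' @examples
#' h <- hypnogram(c("WAKE", "NREM", "REM"), c(0, 100, 400), c(100, 400, 550))
#' state_intervals(h, "NREM")
#' @export
hypnogram <- function(state, start, end,
                      session_start = NULL, session_end = NULL,
                      merge_touching = TRUE) {
  state <- as.character(state)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(state) != length(start) || length(start) != length(end))
    stop("state, start, end must have equal length")
  known <- c("WAKE", "NREM", "REM", "MA")
  bad <- setdiff(unique(state), known)
  if (length(bad)) stop("unknown state label(s): ", paste(bad, collapse = ", "))
  if (any(end <= start)) stop("every interval must satisfy start < end")
  o <- order(start, end)
  state <- state[o]; start <- start[o]; end <- end[o]
  # cross-label overlap check on the raw rows
  if (length(start) > 1L) {
    ov <- which(start[-1L] < end[-length(end)])
    for (i in ov) {
      if (state[i] != state[i + 1L])
        stop(sprintf("overlapping intervals with different labels: %s [%g,%g) vs %s [%g,%g)",
                     state[i], start[i], end[i], state[i + 1L], start[i + 1L], end[i + 1L]))
    }
    if (!merge_touching && length(ov))
      stop("overlapping same-label intervals (merge_touching = FALSE)")
  }
  if (merge_touching && length(start) > 1L) {
    keep_s <- character(0); keep_a <- numeric(0); keep_b <- numeric(0)
    cs <- state[1L]; ca <- start[1L]; cb <- end[1L]
    for (i in seq_along(start)[-1L]) {
      if (state[i] == cs && start[i] <= cb) {
        cb <- max(cb, end[i])
      } else {
        keep_s <- c(keep_s, cs); keep_a <- c(keep_a, ca); keep_b <- c(keep_b, cb)
        cs <- state[i]; ca <- start[i]; cb <- end[i]
      }
    }
    state <- c(keep_s, cs); start <- c(keep_a, ca); end <- c(keep_b, cb)
  }
  if (is.null(session_start)) session_start <- if (length(start)) min(start) else 0
  if (is.null(session_end)) session_end <- if (length(end)) max(end) else 0
  if (length(start) && (min(start) < session_start || max(end) > session_end))
    stop("labeled intervals extend beyond the session bounds")
  structure(
    data.frame(state = state, start = start, end = end,
               stringsAsFactors = FALSE, row.names = NULL),
    session_start = session_start,
    session_end = session_end,
    class = c("hypnogram", "data.frame")
  )
}

#' @rdname hypnogram
#' @param x Object to test.
#' @export
is_hypnogram <- function(x) inherits(x, "hypnogram")

#' Intervals of one state as an interval set
#'
#' @param h A `hypnogram`.
#' @param state State label (`"WAKE"`, `"NREM"`, `"REM"` or `"MA"`).
#' @param merge Merge touching intervals of the state (default `FALSE`:
#'   each scored bout stays a separate epoch candidate).
#' @return An `interval_set` labeled with the state.
#' @export
state_intervals <- function(h, state, merge = FALSE) {
  stopifnot(is_hypnogram(h))
  rows <- h[h$state == state, , drop = FALSE]
  interval_set(rows$start, rows$end, label = state, merge = merge)
}

#' Session bounds of a hypnogram
#' @param h A `hypnogram`.
#' @return Numeric length-2 vector `(session_start, session_end)`.
#' @export
session_bounds <- function(h) {
  stopifnot(is_hypnogram(h))
  c(attr(h, "session_start"), attr(h, "session_end"))
}

#' @export
print.hypnogram <- function(x, ...) {
  b <- session_bounds(x)
  cat(sprintf("<hypnogram: %d interval(s) on [%g, %g) s>\n", nrow(x), b[1], b[2]))
  tb <- tapply(x$end - x$start, x$state, sum)
  for (s in names(tb)) cat(sprintf("  %-4s %10.1f s\n", s, tb[[s]]))
  invisible(x)
}

#' Regularly sampled signal trace
#'
#' Carrier for EMG power or LFP band power used by the substate detectors.
#' Power derivation from raw signals is upstream; the trace is an input.
#'
#' @param start_s Time of the first sample, s.
#' @param step_s Sampling step, s (> 0).
#' @param values Numeric vector of finite sample values (arbitrary units).
#' @param kind `"emg_power"` or `"lfp_band_power"`.
#' @return Object of class `signal_trace`.
#' @export
signal_trace <- function(start_s, step_s, values,
                         kind = c("emg_power", "lfp_band_power")) {
  kind <- match.arg(kind)
  step_s <- as.numeric(step_s)
  values <- as.numeric(values)
  if (!is.finite(step_s) || step_s <= 0) stop("step_s must be > 0")
  if (any(!is.finite(values))) stop("trace values must be finite")
  structure(
    list(start_s = as.numeric(start_s), step_s = step_s,
         values = values, kind = kind),
    class = "signal_trace"
  )
}

#' Sample times of a signal trace
#' @param x A `signal_trace`.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "signal_trace"))
  x$start_s + (seq_along(x$values) - 1L) * x$step_s
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace '%s': %d samples @ %g s from t = %g s>\n",
              x$kind, length(x$values), x$step_s, x$start_s))
  invisible(x)
}
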