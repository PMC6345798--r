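#' Substate detection configuration
#'
#' Defaults follow the field's conventions: population silence longer than
#' 75 ms is an OFF state; a transient EMG elevation between 0.1 s and 40 s
#' inside NREM is a microarousal; LOW states are sustained drops of broadband
#' (0.625--50 Hz) LFP power, with the per-session threshold taken from the
#' valley of the bimodal log-power histogram within NREM.
#'
#' @param off_min_gap_s OFF states are population gaps strictly longer than
#'   this, s.
#' @param off_min_units Below this unit count OFF detection warns that
#'   population silence is weakly informative (still runs).
#' @param ma_min_s,ma_max_s Microarousal duration window, s (strict bounds).
#' @param ma_threshold_mode `"mean_plus_k_sd"` (threshold = NREM mean +
#'   `ma_k` SD) or `"histogram_valley"`.
#' @param ma_k SD multiplier for the EMG threshold.
#' @param ma_smooth_s Optional moving-average width applied to the EMG trace
#'   before thresholding (0 = none).
#' @param low_band Broadband limits, Hz; metadata only (the power trace is an
#'   input).
#' @param low_window_s,low_step_s Window/step the power trace is expected to
#'   have been computed with; metadata only.
#' @param low_threshold_mode `"histogram_valley"` or `"percentile_fallback"`.
#' @param low_fallback_pct Percentile (0--100) of NREM log power used when the
#'   histogram is unimodal.
#' @param low_hist_bins,low_hist_bw_bins Histogram bins and Gaussian smoothing
#'   bandwidth (in bins) for valley detection.
#' @return List of class `detection_config`.
#' @export
detection_config <- function(off_min_gap_s = 0.075, off_min_units = 10L,
                             ma_min_s = 0.1, ma_max_s = 40,
                             ma_threshold_mode = c("mean_plus_k_sd", "histogram_valley"),
                             ma_k = 0.5, ma_smooth_s = 0,
                             low_band = c(0.625, 50),
                             low_window_s = 1.0, low_step_s = 0.1,
                             low_threshold_mode = c("histogram_valley", "percentile_fallback"),
                             low_fallback_pct = 10,
                             low_hist_bins = 100L, low_hist_bw_bins = 3) {
  stopifnot(off_min_gap_s > 0, ma_min_s > 0, ma_max_s > ma_min_s,
            low_window_s > 0, low_step_s > 0)
  structure(list(
    off_min_gap_s = off_min_gap_s, off_min_units = off_min_units,
    ma_min_s = ma_min_s, ma_max_s = ma_max_s,
    ma_threshold_mode = match.arg(ma_threshold_mode), ma_k = ma_k,
    ma_smooth_s = ma_smooth_s,
    low_band = low_band, low_window_s = low_window_s, low_step_s = low_step_s,
    low_threshold_mode = match.arg(low_threshold_mode),
    low_fallback_pct = low_fallback_pct,
    low_hist_bins = low_hist_bins, low_hist_bw_bins = low_hist_bw_bins
  ), class = "detection_config")
}

#' Detect OFF states (population silence) within NREM
#'
#' An OFF state is a gap in the pooled population spike train, inside one
#' NREM interval, strictly longer than `cfg$off_min_gap_s` (75 ms default).
#' Both flanks must be spikes within the same NREM interval: gaps abutting an
#' epoch boundary are not emitted, since boundary silence conflates state
#' transitions with OFF states.
#'
#' @param spikes A [spike_table] (all units are pooled).
#' @param nrem An `interval_set` of NREM intervals.
#' @param cfg A [detection_config].
#' @return `interval_set` labeled `"OFF"`.
#' @export
detect_off_states <- function(spikes, nrem, cfg = detection_config()) {
  stopifnot(is_spike_table(spikes))
  nrem <- as_interval_set(nrem)
  pool <- pooled_spikes(spikes)
  if (!length(pool)) stop("spike table contains no spikes")
  if (n_units(spikes) < cfg$off_min_units)
    warning(sprintf("only %d units: population silence is weakly informative",
                    n_units(spikes)))
  rs <- numeric(0); re <- numeric(0)
  for (r in seq_len(nrow(nrem))) {
    t <- pool[pool >= nrem$start[r] & pool < nrem$end[r]]
    if (length(t) < 2L) next
    g <- diff(t)
    hit <- which(g > cfg$off_min_gap_s)
    rs <- c(rs, t[hit]); re <- c(re, t[hit + 1L])
  }
  # the silent gap is open, (t_last, t_next): in the half-open representation
  # the left edge is nudged 1 ns past the flanking spike so that excluding
  # OFF time never removes the spike itself
  interval_set(rs + 1e-9, re, label = "OFF", merge = FALSE)
}

moving_average <- function(v, width) {
  if (width <= 1L) return(v)
  k <- rep(1 / width, width)
  as.numeric(stats::filter(v, k, sides = 2))
}

# maximal runs of TRUE in a logical vector over a regular grid -> intervals
runs_to_intervals <- function(flag, times, step) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(interval_set())
  interval_set(times[starts[keep]], times[ends[keep]] + step, merge = FALSE)
}

#' Detect microarousals within NREM from an EMG trace
#'
#' The per-session threshold is either NREM mean + `ma_k` SD of the EMG power
#' (default) or the valley of its bimodal histogram. Maximal supra-threshold
#' runs restricted to NREM whose duration is strictly between `ma_min_s` and
#' `ma_max_s` are returned.
#'
#' @param emg A [signal_trace] of kind `"emg_power"` covering the NREM
#'   intervals.
#' @param nrem `interval_set` of NREM intervals.
#' @param cfg A [detection_config].
#' @return `interval_set` labeled `"MA"`.
#' @export
detect_microarousals <- function(emg, nrem, cfg = detection_config()) {
  stopifnot(inherits(emg, "signal_trace"))
  nrem <- as_interval_set(nrem)
  times <- trace_times(emg)
  v <- emg$values
  if (cfg$ma_smooth_s > 0)
    v <- moving_average(v, max(1L, round(cfg$ma_smooth_s / emg$step_s)))
  in_nrem <- iv_contains(times, nrem)
  if (!any(in_nrem)) stop("EMG trace does not cover the NREM intervals")
  thr <- NULL
  if (cfg$ma_threshold_mode == "histogram_valley") {
    thr <- histogram_valley(v[in_nrem], cfg$low_hist_bins, cfg$low_hist_bw_bins)
    if (is.na(thr)) {
      warning("EMG histogram unimodal; falling back to mean + k*SD threshold")
      thr <- NULL
    }
  }
  if (is.null(thr))
    thr <- mean(v[in_nrem]) + cfg$ma_k * stats::sd(v[in_nrem])
  runs <- runs_to_intervals(v > thr & in_nrem, times, emg$step_s)
  runs <- interval_intersect(runs, nrem)
  d <- runs$end - runs$start
  # strict duration window; 1 ns guard absorbs grid-arithmetic rounding
  keep <- d > cfg$ma_min_s + 1e-9 & d < cfg$ma_max_s - 1e-9
  interval_set(runs$start[keep], runs$end[keep], label = "MA", merge = FALSE)
}

# Valley of a kernel-smoothed histogram between its two largest modes.
# Returns NA when the smoothed histogram has fewer than two modes.
histogram_valley <- function(x, n_bins = 100L, bw_bins = 3) {
  if (length(unique(x)) < 3L) return(NA_real_)
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  counts <- h$counts
  if (length(counts) < 5L) return(NA_real_)
  # Gaussian smoothing with bandwidth bw_bins (in bins)
  half <- ceiling(3 * bw_bins)
  kern <- stats::dnorm(-half:half, sd = bw_bins)
  kern <- kern / sum(kern)
  padded <- c(rep(counts[1L], half), counts, rep(counts[length(counts)], half))
  sm <- as.numeric(stats::filter(padded, kern, sides = 2))
  sm <- sm[(half + 1L):(half + length(counts))]
  n <- length(sm)
  is_peak <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] & sm[2:(n - 1)] >= sm[3:n], FALSE)
  peaks <- which(is_peak)
  if (length(peaks) < 2L) return(NA_real_)
  top2 <- peaks[order(sm[peaks], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(sm[lo:hi]) - 1L
  h$mids[valley]
}

#' Detect LOW states within NREM from a band-power trace
#'
#' The trace is expected to be broadband (0.625--50 Hz) LFP power in sliding
#' 1-s windows at 0.1-s steps; computing it from raw LFP is out of scope. The
#' per-session threshold is the valley of a kernel-smoothed histogram (100
#' bins, Gaussian bandwidth 3 bins) of log10 power within NREM between its
#' two largest modes; when the histogram is unimodal the threshold falls back
#' to a percentile of NREM log power (default 10th) with a warning. Maximal
#' sub-threshold runs within NREM are returned.
#'
#' @param power A [signal_trace] of kind `"lfp_band_power"` covering NREM.
#' @param nrem `interval_set` of NREM intervals.
#' @param cfg A [detection_config].
#' @return `interval_set` labeled `"LOW"`.
#' @export
detect_low_states <- function(power, nrem, cfg = detection_config()) {
  stopifnot(inherits(power, "signal_trace"))
  nrem <- as_interval_set(nrem)
  times <- trace_times(power)
  in_nrem <- iv_contains(times, nrem)
  covered <- interval_intersect(
    interval_set(times[1L], times[length(times)] + power$step_s), nrem)
  if (iv_duration(covered) < iv_duration(nrem) - power$step_s)
    stop("power trace does not cover the NREM intervals")
  lv <- log10(pmax(power$values, .Machine$double.xmin))
  thr <- NA_real_
  if (cfg$low_threshold_mode == "histogram_valley")
    thr <- histogram_valley(lv[in_nrem], cfg$low_hist_bins, cfg$low_hist_bw_bins)
  if (is.na(thr)) {
    if (cfg$low_threshold_mode == "histogram_valley")
      warning("log-power histogram unimodal; using percentile fallback threshold")
    thr <- stats::quantile(lv[in_nrem], cfg$low_fallback_pct / 100, names = FALSE)
  }
  runs <- runs_to_intervals(lv < thr & in_nrem, times, power$step_s)
  runs <- interval_intersect(runs, nrem)
  if (nrow(runs) == 0L) return(interval_set(label = "LOW"))
  interval_set(runs$start, runs$end, label = "LOW", merge = FALSE)
}

#' NREM exclusion mask
#'
#' NREM minus the union of the given substate sets. Overlapping substates are
#' subtracted once (union first), so time is conserved:
#' `iv_duration(nrem) == iv_duration(mask) + iv_duration(nrem intersect union)`.
#'
#' @param nrem `interval_set` of NREM intervals.
#' @param ... One or more substate `interval_set`s (OFF/LOW/MA), or a single
#'   list of them.
#' @return `interval_set`: the masked NREM time.
#' @export
exclusion_mask <- function(nrem, ...) {
  nrem <- as_interval_set(nrem)
  subs <- list(...)
  if (length(subs) == 1L && is.list(subs[[1L]]) && !is.data.frame(subs[[1L]]))
    subs <- subs[[1L]]
  if (!length(subs)) return(nrem)
  u <- interval_set()
  for (s in subs) u <- interval_union(u, s)
  interval_subtract(nrem, u, label = attr(nrem, "label"))
}
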