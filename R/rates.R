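#' Per-unit mean firing rates over a mask
#'
#' The elementary rate measurement: spike count inside the mask divided by
#' the mask's occupied duration, per unit. All period rates (FR_i, FR_j,
#' FR_k) reduce to this.
#'
#' @param spikes A [spike_table].
#' @param mask An `interval_set` (or `(start, end)` pair) defining the period,
#'   possibly with substate time excluded.
#' @return Named numeric vector, Hz, one element per unit.
#' @export
period_rates <- function(spikes, mask) {
  stopifnot(is_spike_table(spikes))
  mask <- as_interval_set(mask)
  dur <- iv_duration(mask)
  if (dur <= 0) stop("mask has zero duration")
  vapply(spikes$spikes,
         function(t) count_spikes_in(t, mask)$count / dur,
         numeric(1))
}

#' Sliding-window firing rates
#'
#' Rates of every unit in windows `[t0 + k*step, t0 + k*step + window)`
#' (1-min windows at 20-s steps by default). When a mask is supplied each
#' window is clipped to it and rates are occupancy-corrected; windows whose
#' occupancy falls below `min_occupancy` of the window length are omitted.
#'
#' @param spikes A [spike_table].
#' @param bounds Numeric `(start, end)` session bounds, s.
#' @param window_s,step_s Window length and step, s (`window_s >= step_s > 0`).
#' @param mask Optional `interval_set` restricting analyzed time.
#' @param min_occupancy Minimum occupied fraction for a window to be reported.
#' @return A `rate_matrix`: list with `rates` (units x windows, Hz),
#'   `bin_centers_s`, `occupancy_s`, `unit_ids`, `cell_class`.
#' @export
sliding_rates <- function(spikes, bounds, window_s = 60, step_s = 20,
                          mask = NULL, min_occupancy = 0.1) {
  stopifnot(is_spike_table(spikes), window_s >= step_s, step_s > 0)
  bounds <- as.numeric(bounds)
  if (length(bounds) != 2L || bounds[2] <= bounds[1])
    stop("bounds must be (start, end) with end > start")
  starts <- seq(bounds[1], bounds[2] - window_s, by = step_s)
  if (!length(starts)) stop("session shorter than one window")
  wins <- lapply(starts, function(s) {
    w <- interval_set(s, s + window_s)
    if (!is.null(mask)) w <- interval_intersect(w, mask)
    w
  })
  occ <- vapply(wins, iv_duration, numeric(1))
  keep <- occ >= min_occupancy * window_s
  wins <- wins[keep]; occ <- occ[keep]; starts <- starts[keep]
  rates <- matrix(0, n_units(spikes), length(wins),
                  dimnames = list(spikes$units$unit_id, NULL))
  for (j in seq_along(wins)) {
    for (i in seq_len(n_units(spikes)))
      rates[i, j] <- count_spikes_in(spikes$spikes[[i]], wins[[j]])$count / occ[j]
  }
  structure(list(rates = rates, bin_centers_s = starts + window_s / 2,
                 occupancy_s = occ, unit_ids = spikes$units$unit_id,
                 cell_class = spikes$units$cell_class),
            class = "rate_matrix")
}

#' Time-normalized epoch rates
#'
#' Partitions an epoch into `n_bins` equal-duration half-open bins (30 for
#' NREM, 10 for REM in the standard analysis, since NREM epochs run longer)
#' and computes occupancy-corrected per-unit rates per bin. Bins whose masked
#' occupancy falls below `min_occupancy` of the bin width are reported as
#' `NA` (missing), never as zero.
#'
#' @param spikes A [spike_table].
#' @param epoch Numeric `(start, end)`, s.
#' @param n_bins Number of equal-duration bins (>= 1).
#' @param mask Optional `interval_set` of retained time.
#' @param min_occupancy Minimum occupied fraction for a bin to be reported.
#' @return A `rate_matrix` (see [sliding_rates()]); omitted bins are `NA`.
#' @export
time_normalized_rates <- function(spikes, epoch, n_bins, mask = NULL,
                                  min_occupancy = 0.1) {
  stopifnot(is_spike_table(spikes), n_bins >= 1L)
  epoch <- as.numeric(epoch)
  d <- epoch[2] - epoch[1]
  if (d <= 0) stop("epoch duration must be > 0")
  b <- epoch[1] + d * (0:n_bins) / n_bins
  b[n_bins + 1L] <- epoch[2]
  rates <- matrix(NA_real_, n_units(spikes), n_bins,
                  dimnames = list(spikes$units$unit_id, NULL))
  occ <- numeric(n_bins)
  width <- d / n_bins
  for (j in seq_len(n_bins)) {
    w <- interval_set(b[j], b[j + 1L])
    if (!is.null(mask)) w <- interval_intersect(w, mask)
    occ[j] <- iv_duration(w)
    if (occ[j] < min_occupancy * width) next
    for (i in seq_len(n_units(spikes)))
      rates[i, j] <- count_spikes_in(spikes$spikes[[i]], w)$count / occ[j]
  }
  structure(list(rates = rates,
                 bin_centers_s = (b[-(n_bins + 1L)] + b[-1L]) / 2,
                 occupancy_s = occ, unit_ids = spikes$units$unit_id,
                 cell_class = spikes$units$cell_class),
            class = "rate_matrix")
}

#' Assign principal cells to firing-rate quintiles
#'
#' Cells are ranked ascending by rate; the cell of 1-based rank `r` among `n`
#' gets quintile `ceiling(5 r / n)`, so group sizes differ by at most one and
#' the assignment is a deterministic function of the rate vector and unit
#' ids. Ties (including multiple zero-rate cells) break by ascending unit id,
#' making re-runs reproducible. Interneurons are never quintiled: pass
#' principal-cell rates only.
#'
#' @param rates Per-cell rates, Hz.
#' @param unit_ids Unit ids aligned with `rates` (used for tie-breaks and
#'   names). Defaults to `names(rates)`.
#' @param n_groups Number of rank groups (default 5).
#' @return Integer vector of group indices (1 = lowest-firing), named by unit.
#' @export
assign_quintiles <- function(rates, unit_ids = names(rates), n_groups = 5L) {
  n <- length(rates)
  if (n < n_groups) stop(sprintf("need at least %d cells, got %d", n_groups, n))
  if (is.null(unit_ids)) unit_ids <- as.character(seq_len(n))
  o <- order(rates, unit_ids)
  rank <- integer(n); rank[o] <- seq_len(n)
  q <- as.integer(ceiling(n_groups * rank / n))
  names(q) <- unit_ids
  q
}

#' Per-quintile mean traces, raw and reference-normalized
#'
#' Averages a rate matrix within each quintile (and, when interneurons are
#' present in the matrix, as one separate group) per bin, then normalizes
#' each group trace by its mean over the reference bins -- conventionally the
#' last third of the first state -- so each normalized trace averages exactly
#' 1 over the reference. Groups whose reference mean is zero are flagged
#' (`NA` normalized trace), never divided.
#'
#' @param rm A `rate_matrix` from [sliding_rates()] or
#'   [time_normalized_rates()].
#' @param assignment Quintile assignment from [assign_quintiles()] for the
#'   principal cells in `rm` (named by unit id).
#' @param reference_bins Integer indices of the reference bins.
#' @return List with `raw` and `normalized` (groups x bins matrices, row
#'   names `q1`..`q5` and `interneuron` when present), `reference_bins`, and
#'   `flagged` (groups with zero reference mean).
#' @export
quintile_traces <- function(rm, assignment, reference_bins) {
  stopifnot(inherits(rm, "rate_matrix"))
  groups <- character(nrow(rm$rates))
  pc <- rm$cell_class == "principal"
  m <- match(rm$unit_ids[pc], names(assignment))
  if (anyNA(m)) stop("assignment does not cover all principal cells")
  groups[pc] <- paste0("q", assignment[m])
  groups[!pc] <- "interneuron"
  lev <- c(paste0("q", sort(unique(assignment))),
           if (any(!pc)) "interneuron")
  raw <- t(vapply(lev, function(g) {
    colMeans(rm$rates[groups == g, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(rm$rates))))
  ref <- rowMeans(raw[, reference_bins, drop = FALSE], na.rm = TRUE)
  flagged <- rownames(raw)[!is.na(ref) & ref == 0]
  norm <- raw / ifelse(ref == 0, NA_real_, ref)
  list(raw = raw, normalized = norm, reference_bins = reference_bins,
       flagged = flagged)
}

#' Population coefficient of variation
#'
#' CV = sample SD (n-1 denominator) / mean of per-cell rates, the standard
#' width measure of the population rate distribution: it rises when the
#' distribution widens (REM) and falls when it homogenizes (NREM).
#'
#' @param rates Per-cell rates, Hz (principal cells by convention).
#' @return List: `cv` (`NA` with `undefined = TRUE` if the mean is 0),
#'   `n_cells`, `undefined`.
#' @export
population_cv <- function(rates) {
  rates <- rates[!is.na(rates)]
  if (length(rates) < 2L) stop("need at least 2 cells")
  m <- mean(rates)
  if (m == 0) return(list(cv = NA_real_, n_cells = length(rates), undefined = TRUE))
  list(cv = stats::sd(rates) / m, n_cells = length(rates), undefined = FALSE)
}
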