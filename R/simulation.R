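#' Log-normal parameters from linear-scale moments
#'
#' Given the linear-scale mean and SD of a log-normal variable, returns the
#' `(mu, sigma)` of the underlying normal: `sigma^2 = log(1 + sd^2/mean^2)`,
#' `mu = log(mean) - sigma^2/2`. The round trip is exact.
#'
#' @param mean_hz Linear mean (> 0).
#' @param sd_hz Linear SD (>= 0); 0 gives a degenerate point mass.
#' @return List with `mu`, `sigma`.
#' @export
lognormal_params_from_moments <- function(mean_hz, sd_hz) {
  if (!is.finite(mean_hz) || mean_hz <= 0) stop("mean must be > 0")
  if (sd_hz < 0) stop("sd must be >= 0")
  sigma2 <- log(1 + (sd_hz / mean_hz)^2)
  list(mu = log(mean_hz) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Population simulation configuration
#'
#' The reference preset mirrors the statistics of hippocampal pyramidal cells
#' in NREM: 5000 cells with log-normally distributed baseline rates of linear
#' mean 0.59 Hz and SD 0.84 Hz, three epochs (i, j, k), and multiplicative
#' noise -- each epoch's rate is the baseline times `(1 + eps)` with
#' `eps ~ N(0, noise_sd)`, so every cell's noise SD is proportional to its
#' own rate (relative SD 0.35 by default). Negative noisy rates are truncated
#' at 0; with the default noise the clipped fraction is about 0.2% and is
#' reported as an attribute.
#'
#' @param n_cells Number of cells (>= 5).
#' @param baseline_mean_hz,baseline_sd_hz Linear moments of the baseline
#'   log-normal, Hz.
#' @param noise_sd Relative (rate-proportional) noise SD, dimensionless.
#' @param change `"none"`, `"additive"` (epoch j baseline + `delta_hz`) or
#'   `"multiplicative"` (epoch j baseline x `factor`). Epochs i and k always
#'   carry the unchanged baseline.
#' @param delta_hz Additive increase, Hz.
#' @param factor Multiplicative factor (> 0).
#' @param seed RNG seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 5000L, baseline_mean_hz = 0.59,
                              baseline_sd_hz = 0.84, noise_sd = 0.35,
                              change = c("none", "additive", "multiplicative"),
                              delta_hz = 0.05, factor = 1.1, seed = NULL) {
  change <- match.arg(change)
  stopifnot(n_cells >= 5L, baseline_mean_hz > 0, baseline_sd_hz > 0,
            noise_sd >= 0, factor > 0)
  structure(list(n_cells = as.integer(n_cells),
                 baseline_mean_hz = baseline_mean_hz,
                 baseline_sd_hz = baseline_sd_hz,
                 noise_sd = noise_sd, change = change,
                 delta_hz = delta_hz, factor = factor, seed = seed),
            class = "simulation_config")
}

#' Simulate a three-epoch population of firing rates
#'
#' Draws per-cell baselines from the configured log-normal, applies the
#' scenario change to epoch j only, and adds independent rate-proportional
#' noise per epoch. Deterministic under the config seed.
#'
#' @param cfg A [simulation_config].
#' @return data.frame of class `epoch_rate_table`: `cell_id`, `baseline_hz`,
#'   `fr_i`, `fr_j`, `fr_k` (Hz); attribute `clipped_fraction` = share of
#'   rate values truncated at 0.
#' @export
simulate_population <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  lp <- lognormal_params_from_moments(cfg$baseline_mean_hz, cfg$baseline_sd_hz)
  rel_sd <- cfg$noise_sd
  with_seed(cfg$seed, {
    b <- stats::rlnorm(cfg$n_cells, lp$mu, lp$sigma)
    bj <- switch(cfg$change,
                 none = b,
                 additive = b + cfg$delta_hz,
                 multiplicative = b * cfg$factor)
    noisy <- function(base) base * (1 + stats::rnorm(cfg$n_cells, 0, rel_sd))
    raw <- cbind(i = noisy(b), j = noisy(bj), k = noisy(b))
    clipped <- mean(raw < 0)
    raw[raw < 0] <- 0
    ids <- sprintf("c%05d", seq_len(cfg$n_cells))
    out <- data.frame(cell_id = ids, baseline_hz = b,
                      fr_i = raw[, "i"], fr_j = raw[, "j"], fr_k = raw[, "k"],
                      stringsAsFactors = FALSE)
    attr(out, "clipped_fraction") <- clipped
    class(out) <- c("epoch_rate_table", "data.frame")
    out
  })
}

#' Run the three simulated change scenarios
#'
#' For each scenario (no change, additive +0.05 Hz, multiplicative x1.1):
#' simulate the population, assign quintiles on the epoch-i rates, compute
#' the observed quintile CI between i and j, build the i/k flip surrogates,
#' and derive the deflection index with 95% bands. The no-change scenario
#' shows the raw-CI RTM artifact (apparent rise in low, fall in high
#' quintiles) while every DI stays inside its band; the additive scenario
#' yields a quintile-graded DI; the multiplicative scenario a flat DI near
#' `(1 - factor) / (1 + factor)`.
#'
#' @param scenarios Character vector of scenarios to run.
#' @param n_shuffles Surrogates per scenario.
#' @param seed Base RNG seed; scenario s uses `seed + s - 1` for its
#'   population and surrogates.
#' @param ... Passed to [simulation_config()] (e.g. `n_cells`).
#' @return Named list per scenario: `di` ([deflection_index()] table), `ci`
#'   (`ci_result`), `surrogates` (the `surrogate_distribution`), `rates` (the
#'   simulated table).
#' @export
run_change_scenarios <- function(scenarios = c("none", "additive", "multiplicative"),
                                 n_shuffles = 2000L, seed = 1L, ...) {
  out <- list()
  for (s in seq_along(scenarios)) {
    sc <- scenarios[s]
    cfg <- simulation_config(change = sc, seed = seed + s - 1L, ...)
    pop <- simulate_population(cfg)
    q <- assign_quintiles(stats::setNames(pop$fr_i, pop$cell_id))
    ci <- change_index(pop$fr_i, pop$fr_j, groups = paste0("q", q))
    surr <- shuffle_surrogates(stats::setNames(pop$fr_i, pop$cell_id),
                               stats::setNames(pop$fr_k, pop$cell_id),
                               n_shuffles = n_shuffles,
                               seed = cfg$seed + 10000L)
    out[[sc]] <- list(di = deflection_index(ci, surr), ci = ci,
                      surrogates = surr, rates = pop)
  }
  out
}

#' Synthetic-session specification
#'
#' Defaults emulate the statistical structure the pipeline assumes in real
#' recordings: log-normal baseline rates referenced to NREM, a
#' WAKE/(NREM-REM)xk/WAKE state architecture with log-normal epoch durations,
#' quintile-dependent REM modulation (widening: low quintiles suppressed,
#' high slightly elevated), an interneuron REM gain, and planted OFF/MA/LOW
#' substates inside NREM with matching EMG / band-power traces. Durations are
#' artifact conventions for testing, not measured values.
#'
#' @param n_principal,n_interneuron Unit counts.
#' @param baseline_mean_hz,baseline_sd_hz Principal-cell baseline log-normal
#'   (linear moments, Hz) in NREM.
#' @param interneuron_mean_hz,interneuron_sd_hz Interneuron baseline moments.
#' @param n_cycles Number of NREM-REM cycles per sleep bout.
#' @param n_bouts Number of sleep bouts (separated by long WAKE).
#' @param nrem_mean_s,rem_mean_s,wake_mean_s Log-normal epoch-duration means, s.
#' @param duration_cv Coefficient of variation of epoch durations.
#' @param rem_quintile_factors Length-5 multiplicative REM modulation of
#'   principal quintiles (1 = lowest-firing), applied to the NREM-referenced
#'   baseline.
#' @param wake_factor WAKE modulation of principal cells.
#' @param interneuron_state_gain Named vector of interneuron gains per state.
#' @param epoch_noise_sd Multiplicative rate jitter per (cell, epoch); 0
#'   disables.
#' @param off_rate_per_min Planted OFF states per NREM minute.
#' @param off_duration_s Range of OFF durations, s.
#' @param ma_rate_per_min,ma_duration_s Planted microarousals (rate, duration
#'   range).
#' @param low_rate_per_min,low_duration_s Planted LOW states.
#' @param low_firing_factor Rate multiplier inside LOW states.
#' @param emg_step_s,power_step_s Trace sampling steps, s.
#' @param seed RNG seed.
#' @return List of class `session_spec`.
#' @export
session_spec <- function(n_principal = 80L, n_interneuron = 10L,
                         baseline_mean_hz = 0.59, baseline_sd_hz = 0.84,
                         interneuron_mean_hz = 12, interneuron_sd_hz = 6,
                         n_cycles = 4L, n_bouts = 2L,
                         nrem_mean_s = 600, rem_mean_s = 180, wake_mean_s = 900,
                         duration_cv = 0.3,
                         rem_quintile_factors = c(0.6, 0.8, 0.9, 1.0, 1.1),
                         wake_factor = 1.0,
                         interneuron_state_gain = c(NREM = 1, REM = 1.3, WAKE = 1.1),
                         epoch_noise_sd = 0.1,
                         off_rate_per_min = 0, off_duration_s = c(0.08, 0.3),
                         ma_rate_per_min = 0, ma_duration_s = c(1, 10),
                         low_rate_per_min = 0, low_duration_s = c(5, 20),
                         low_firing_factor = 0.3,
                         emg_step_s = 0.1, power_step_s = 0.1, seed = NULL) {
  stopifnot(n_principal >= 5L, length(rem_quintile_factors) == 5L,
            all(rem_quintile_factors > 0), low_firing_factor >= 0)
  spec <- as.list(environment())
  structure(spec, class = "session_spec")
}

draw_duration <- function(n, mean_s, cv) {
  lp <- lognormal_params_from_moments(mean_s, cv * mean_s)
  stats::rlnorm(n, lp$mu, lp$sigma)
}

# plant non-overlapping sub-intervals of the given durations inside
# [start, end), a margin off the edges; grid_s > 0 snaps bounds to the trace
# grid so detectors can recover the planted edges exactly
plant_intervals <- function(start, end, rate_per_min, dur_range, margin = 1,
                            grid_s = 0) {
  avail <- end - start - 2 * margin
  if (avail <= max(dur_range)) return(NULL)
  n <- stats::rpois(1L, rate_per_min * (end - start) / 60)
  if (n == 0L) return(NULL)
  out <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(out) < n && tries < 50L * n) {
    tries <- tries + 1L
    d <- stats::runif(1L, dur_range[1], dur_range[2])
    s <- stats::runif(1L, start + margin, end - margin - d)
    if (grid_s > 0) {
      s <- round(s / grid_s) * grid_s
      d <- max(grid_s, round(d / grid_s) * grid_s)
    }
    if (!nrow(out) || all(s + d <= out[, 1] - 0.2 | s >= out[, 2] + 0.2))
      out <- rbind(out, c(s, s + d))
  }
  out
}

# homogeneous Poisson spikes on [a, b) at rate lambda
rpois_spikes <- function(a, b, lambda) {
  if (lambda <= 0 || b <= a) return(numeric(0))
  n <- stats::rpois(1L, lambda * (b - a))
  if (!n) return(numeric(0))
  sort(stats::runif(n, a, b))
}

#' Generate a full synthetic session
#'
#' Builds a hypnogram (no WAKE-to-REM transitions), inhomogeneous-Poisson
#' spike trains with intensity = baseline x state modulation x substate
#' gating (zero inside planted OFF states, `low_firing_factor` inside planted
#' LOW states), an EMG trace elevated inside planted microarousals, a
#' band-power trace lowered inside planted LOW states, and a ground-truth
#' ledger of everything planted. Deterministic under the spec seed.
#'
#' @param spec A [session_spec].
#' @return List of class `synthetic_session`: `spikes` ([spike_table]),
#'   `hypnogram` ([hypnogram]), `emg`, `power` ([signal_trace]s), and
#'   `truth` (baselines, true quintiles, modulation table, planted OFF/MA/LOW
#'   `interval_set`s, spec echo).
#' @export
simulate_session <- function(spec = session_spec()) {
  stopifnot(inherits(spec, "session_spec"))
  with_seed(spec$seed, {
    ## hypnogram: WAKE (NREM REM)^n_cycles ... per bout, WAKE between bouts
    st <- character(0); dur <- numeric(0)
    for (b in seq_len(spec$n_bouts)) {
      st <- c(st, "WAKE"); dur <- c(dur, draw_duration(1, spec$wake_mean_s, spec$duration_cv))
      for (cy in seq_len(spec$n_cycles)) {
        st <- c(st, "NREM", "REM")
        dur <- c(dur, draw_duration(1, spec$nrem_mean_s, spec$duration_cv),
                 draw_duration(1, spec$rem_mean_s, spec$duration_cv))
      }
    }
    st <- c(st, "WAKE"); dur <- c(dur, draw_duration(1, spec$wake_mean_s, spec$duration_cv))
    end <- cumsum(dur); start <- c(0, end[-length(end)])
    h <- hypnogram(st, start, end, merge_touching = FALSE)

    ## baselines and true quintiles (by baseline rank)
    lp <- lognormal_params_from_moments(spec$baseline_mean_hz, spec$baseline_sd_hz)
    bp <- stats::rlnorm(spec$n_principal, lp$mu, lp$sigma)
    li <- lognormal_params_from_moments(spec$interneuron_mean_hz, spec$interneuron_sd_hz)
    bi <- if (spec$n_interneuron > 0) stats::rlnorm(spec$n_interneuron, li$mu, li$sigma) else numeric(0)
    pids <- sprintf("p%03d", seq_len(spec$n_principal))
    iids <- if (spec$n_interneuron > 0) sprintf("i%03d", seq_len(spec$n_interneuron)) else character(0)
    qtruth <- assign_quintiles(stats::setNames(bp, pids))

    ## per-unit per-state intensity
    state_mod <- function(unit, state) {
      if (unit <= spec$n_principal) {
        switch(state,
               NREM = 1,
               REM = spec$rem_quintile_factors[qtruth[unit]],
               WAKE = spec$wake_factor)
      } else spec$interneuron_state_gain[[state]]
    }
    base_all <- c(bp, bi)
    n_all <- length(base_all)

    ## plant substates inside NREM epochs
    nrem_rows <- which(st == "NREM")
    off <- NULL; ma <- NULL; low <- NULL
    for (r in nrem_rows) {
      off <- rbind(off, plant_intervals(start[r], end[r], spec$off_rate_per_min,
                                        spec$off_duration_s))
      ma <- rbind(ma, plant_intervals(start[r], end[r], spec$ma_rate_per_min,
                                      spec$ma_duration_s, grid_s = spec$emg_step_s))
      low <- rbind(low, plant_intervals(start[r], end[r], spec$low_rate_per_min,
                                        spec$low_duration_s, grid_s = spec$power_step_s))
    }
    to_iv <- function(m, lab) {
      if (is.null(m) || !nrow(m)) interval_set(label = lab)
      else interval_set(m[, 1], m[, 2], label = lab, merge = FALSE)
    }
    off_iv <- to_iv(off, "OFF"); ma_iv <- to_iv(ma, "MA"); low_iv <- to_iv(low, "LOW")

    ## spike trains: piecewise-constant intensity per (unit, epoch segment)
    spikes <- vector("list", n_all)
    names(spikes) <- c(pids, iids)
    epoch_gain <- if (spec$epoch_noise_sd > 0) {
      matrix(pmax(0, 1 + stats::rnorm(n_all * length(st), 0, spec$epoch_noise_sd)),
             n_all, length(st))
    } else matrix(1, n_all, length(st))
    # per-epoch segment partition (shared across units): each segment has a
    # gating factor -- 0 inside OFF (segments dropped), low_firing_factor
    # inside LOW, 1 elsewhere
    seg_by_epoch <- lapply(seq_along(st), function(r) {
      seg <- interval_set(start[r], end[r])
      if (st[r] == "NREM" && (nrow(off_iv) || nrow(low_iv))) {
        gatelow <- interval_intersect(interval_subtract(seg, off_iv), low_iv)
        clear <- interval_subtract(seg, interval_union(off_iv, low_iv))
        list(start = c(clear$start, gatelow$start),
             end = c(clear$end, gatelow$end),
             gate = c(rep(1, nrow(clear)),
                      rep(spec$low_firing_factor, nrow(gatelow))))
      } else list(start = start[r], end = end[r], gate = 1)
    })
    for (u in seq_len(n_all)) {
      tr <- vector("list", length(st))
      for (r in seq_along(st)) {
        lam <- base_all[u] * state_mod(u, st[r]) * epoch_gain[u, r]
        if (lam <= 0) next
        sg <- seg_by_epoch[[r]]
        len <- sg$end - sg$start
        n_k <- stats::rpois(length(len), lam * sg$gate * len)
        if (sum(n_k) == 0L) next
        tr[[r]] <- stats::runif(sum(n_k), rep(sg$start, n_k), rep(sg$end, n_k))
      }
      spikes[[u]] <- sort(unlist(tr, use.names = FALSE))
    }
    stbl <- spike_table(spikes,
                        region = "synthetic",
                        cell_class = c(rep("principal", spec$n_principal),
                                       rep("interneuron", spec$n_interneuron)))

    ## traces: EMG elevated in WAKE and inside MAs; band power low in LOW
    t_emg <- seq(0, max(end), by = spec$emg_step_s)
    emg_v <- 1 + 0.05 * stats::rnorm(length(t_emg))
    emg_v[iv_contains(t_emg, state_intervals(h, "WAKE"))] <- 3 +
      0.2 * stats::rnorm(sum(iv_contains(t_emg, state_intervals(h, "WAKE"))))
    in_ma <- iv_contains(t_emg, ma_iv)
    emg_v[in_ma] <- 5 + 0.2 * stats::rnorm(sum(in_ma))
    emg <- signal_trace(0, spec$emg_step_s, pmax(emg_v, 0.01), kind = "emg_power")

    t_pow <- seq(0, max(end), by = spec$power_step_s)
    pow_v <- exp(log(10) + 0.15 * stats::rnorm(length(t_pow)))
    in_low <- iv_contains(t_pow, low_iv)
    pow_v[in_low] <- exp(log(10 * 0.05) + 0.15 * stats::rnorm(sum(in_low)))
    power <- signal_trace(0, spec$power_step_s, pow_v, kind = "lfp_band_power")

    structure(list(
      spikes = stbl, hypnogram = h, emg = emg, power = power,
      truth = list(baseline_hz = stats::setNames(c(bp, bi), c(pids, iids)),
                   quintile = qtruth,
                   rem_quintile_factors = spec$rem_quintile_factors,
                   interneuron_state_gain = spec$interneuron_state_gain,
                   off = off_iv, ma = ma_iv, low = low_iv,
                   spec = spec)
    ), class = "synthetic_session")
  })
}
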