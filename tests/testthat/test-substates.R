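two_unit_table <- function(a, b) {
  spike_table(list(u1 = a, u2 = b), cell_class = "principal")
}

test_that("OFF states are strict population gaps with in-epoch flanks", {
  nrem <- interval_set(0, 1, label = "NREM")
  st <- spike_table(list(u1 = c(0.0, 0.2, 0.21)), cell_class = "principal")
  off <- suppressWarnings(detect_off_states(st, nrem))
  expect_equal(as.data.frame(off), data.frame(start = 0.0, end = 0.2),
               ignore_attr = TRUE)

  # a gap of exactly 75 ms is not an OFF state
  st2 <- spike_table(list(u1 = c(0.1, 0.175, 0.2)), cell_class = "principal")
  expect_equal(iv_count(suppressWarnings(detect_off_states(st2, nrem))), 0L)

  # two units alternating every 50 ms: no OFF despite 100-ms within-unit gaps
  a <- seq(0, 1, by = 0.1); b <- seq(0.05, 1, by = 0.1)
  off3 <- suppressWarnings(detect_off_states(two_unit_table(a, b), nrem))
  expect_equal(iv_count(off3), 0L)
  # oracle: brute-force scan of the pooled gaps
  pooled <- sort(c(a, b))
  expect_identical(any(diff(pooled) > 0.075), iv_count(off3) > 0L)

  # boundary gaps (no flanking spike inside the epoch) are not emitted
  st4 <- spike_table(list(u1 = c(0.5)), cell_class = "principal")
  expect_equal(iv_count(suppressWarnings(detect_off_states(st4, nrem))), 0L)
  expect_error(detect_off_states(spike_table(list(u1 = numeric(0))), nrem),
               "no spikes")
})

test_that("microarousal detection applies the strict duration window", {
  nrem <- interval_set(0, 100, label = "NREM")
  base <- function(exc_start, exc_len) {
    v <- rep(1, 1000)  # 0.1-s grid over [0, 100)
    idx <- seq(exc_start / 0.1 + 1, length.out = exc_len / 0.1)
    v[idx] <- 10
    signal_trace(0, 0.1, v, kind = "emg_power")
  }
  ma <- detect_microarousals(base(20, 5), nrem)
  expect_equal(iv_count(ma), 1L)
  expect_equal(as.data.frame(ma), data.frame(start = 20, end = 25),
               tolerance = 1e-9, ignore_attr = TRUE)
  # 45-s excursion exceeds the 40-s cap; 0.05-s blips are under the floor
  expect_equal(iv_count(detect_microarousals(base(20, 45), nrem)), 0L)
  v <- rep(1, 1000); v[300] <- 10  # one elevated sample = 0.1 s, not > 0.1 s
  tr <- signal_trace(0, 0.1, v, kind = "emg_power")
  expect_equal(iv_count(detect_microarousals(tr, nrem)), 0L)
})

test_that("LOW detection recovers planted drops within one step per edge", {
  set.seed(31)
  nrem <- interval_set(0, 600, label = "NREM")
  t <- seq(0, 599.9, by = 0.1)
  lv <- rnorm(length(t), 1, 0.05)           # log10 power around 1
  planted <- interval_set(c(100, 300.5, 472.3), c(112, 315.5, 490.3))
  inlow <- iv_contains(t, planted)
  lv[inlow] <- rnorm(sum(inlow), -0.3, 0.05)
  tr <- signal_trace(0, 0.1, 10^lv, kind = "lfp_band_power")
  low <- detect_low_states(tr, nrem)
  expect_equal(iv_count(low), 3L)
  expect_true(all(abs(low$start - planted$start) <= 0.1 + 1e-9))
  expect_true(all(abs(low$end - planted$end) <= 0.1 + 1e-9))

  # constant power: unimodal histogram exercises the percentile fallback
  flat <- signal_trace(0, 0.1, rep(5, length(t)), kind = "lfp_band_power")
  expect_warning(low2 <- detect_low_states(flat, nrem), "unimodal")
  expect_true(iv_count(low2) >= 0L)
})

test_that("exclusion masks subtract substate unions exactly once", {
  nrem <- interval_set(0, 100, label = "NREM")
  off <- interval_set(10, 10.2, label = "OFF")
  expect_equal(iv_duration(exclusion_mask(nrem, off)), 99.8)
  expect_equal(as.data.frame(exclusion_mask(nrem)), as.data.frame(nrem))

  # overlapping OFF and LOW subtract once, verified against the grid oracle
  low <- interval_set(10.1, 12, label = "LOW")
  m <- exclusion_mask(nrem, off, low)
  g_n <- grid_coverage(nrem, 100); g_o <- grid_coverage(off, 100)
  g_l <- grid_coverage(low, 100)
  expect_identical(grid_coverage(m, 100), g_n & !(g_o | g_l))
  expect_equal(iv_duration(m), 100 - 2, tolerance = 1e-9)
})

test_that("removing OFF time never lowers any unit's NREM rate", {
  set.seed(17)
  sp <- session_spec(n_principal = 20, n_interneuron = 4, n_cycles = 2,
                     n_bouts = 1, nrem_mean_s = 300, rem_mean_s = 150,
                     wake_mean_s = 200, off_rate_per_min = 1, seed = 23)
  ss <- simulate_session(sp)
  nrem <- state_intervals(ss$hypnogram, "NREM")
  off <- suppressWarnings(detect_off_states(ss$spikes, nrem))
  r0 <- period_rates(ss$spikes, nrem)
  r1 <- period_rates(ss$spikes, exclusion_mask(nrem, off))
  expect_true(all(r1 >= r0 - 1e-12))
  expect_true(all(iv_contains(off$start + 1e-9, nrem)))  # OFF lies inside NREM
})
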