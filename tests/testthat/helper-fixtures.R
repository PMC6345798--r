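# Shared fixtures and independent oracles, built in code at test time.

# brute-force membership oracle on a regular grid (default 1 ms)
grid_coverage <- function(iv, t_max, step = 1e-3) {
  g <- seq(step / 2, t_max, by = step)  # midpoints avoid boundary ambiguity
  iv_contains(g, iv)
}

random_interval_family <- function(n_max = 6, t_max = 5) {
  n <- sample.int(n_max, 1L)
  s <- sort(runif(n, 0, t_max * 0.9))
  e <- s + runif(n, 0.05, t_max / 3)
  interval_set(s, pmin(e, t_max))
}

# regular-spiking toy table: one principal unit at `rate` Hz on [0, dur)
regular_unit <- function(rate = 10, dur = 300, id = "u1") {
  spike_table(stats::setNames(list(seq(0, dur - 1e-9, by = 1 / rate)), id),
              region = "hpc", cell_class = "principal")
}

# small deterministic hypnogram: W, N, R, N, W (all passing filters)
toy_hypnogram <- function() {
  hypnogram(c("WAKE", "NREM", "REM", "NREM", "WAKE"),
            c(0, 200, 500, 650, 950),
            c(200, 500, 650, 950, 1150))
}

# exhaustive flip-pattern oracle for the surrogate distribution: enumerates
# all 2^n i/k assignments, re-deriving quintiles per pattern, and returns the
# exact distribution of group CIs (each pattern equally likely)
exhaustive_flip_oracle <- function(fr_i, fr_k, unit_ids, n_groups = 5L) {
  n <- length(fr_i)
  stopifnot(n <= 14)
  pat <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vals <- matrix(NA_real_, nrow(pat), n_groups)
  for (p in seq_len(nrow(pat))) {
    fl <- pat[p, ]
    si <- ifelse(fl, fr_k, fr_i)
    sk <- ifelse(fl, fr_i, fr_k)
    q <- assign_quintiles(stats::setNames(si, unit_ids), n_groups = n_groups)
    for (g in seq_len(n_groups)) {
      mi <- mean(si[q == g]); mk <- mean(sk[q == g])
      vals[p, g] <- (mi - mk) / (mi + mk)
    }
  }
  colnames(vals) <- paste0("q", seq_len(n_groups))
  vals
}
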