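#' End-to-end transition analysis
#'
#' Runs the full analysis for each requested sequence kind: duration-filter
#' epochs, extract sequences and control periods, compute per-cell period
#' rates (optionally on exclusion-masked time), apply the sequence-level
#' non-firing rule, assign quintiles on the epoch-i rates, compute the
#' observed CI, the i/k flip surrogates and the deflection index per
#' sequence, and aggregate: per-group mean DI with a signed-rank test across
#' sequences, the delta-CV trajectory with its signed-rank test, a
#' Kolmogorov-Smirnov comparison of the pooled rate distributions, a one-way
#' ANOVA of per-cell CI across quintiles, and a cell-epoch accounting table.
#' Deterministic given inputs and `seed`.
#'
#' @param spikes A [spike_table].
#' @param h A [hypnogram].
#' @param kinds Sequence kinds to analyze (see [extract_sequences()]).
#' @param exclude Optional `interval_set` of time to remove from every
#'   analysis period (e.g. an OFF/LOW/MA union), or `NULL`.
#' @param min_nrem_s,min_rem_s Epoch duration filters, s (strict `>`).
#' @param nonfiring_threshold Sequence-level silent-cell fraction rule.
#' @param n_shuffles Surrogates per sequence.
#' @param seed Base RNG seed; recorded in the bundle.
#' @param same_bout,max_gap_s,max_wake_interruption_s Sequence/control
#'   selection options (see [extract_sequences()],
#'   [select_control_period()]).
#' @return List of class `analysis_bundle`, one element per kind, each with
#'   `sequences` (the sequence table with exclusion flags), `di_by_sequence`
#'   (long table of per-sequence DI rows), `di_summary` (per-group mean DI +
#'   signed-rank p across sequences), `dcv` (per-sequence delta-CV),
#'   `dcv_test`, `ks_test`, `anova_quintile_ci`, `accounting`; plus a
#'   top-level `config` echo.
#' @export
run_transition_analysis <- function(spikes, h, kinds = "NREM_REM",
                                    exclude = NULL,
                                    min_nrem_s = 150, min_rem_s = 100,
                                    nonfiring_threshold = 0.20,
                                    n_shuffles = 2000L, seed = 1L,
                                    same_bout = TRUE, max_gap_s = Inf,
                                    max_wake_interruption_s = 60) {
  stopifnot(is_spike_table(spikes), is_hypnogram(h))
  epochs <- filter_epochs(h, min_nrem_s, min_rem_s)
  pc <- spikes$units$cell_class == "principal"
  out <- list()
  for (kind in kinds) {
    seqs <- extract_sequences(epochs, kind, max_gap_s = max_gap_s,
                              max_wake_interruption_s = max_wake_interruption_s)
    seqs <- select_control_period(seqs, epochs, same_bout = same_bout,
                                  max_wake_interruption_s = max_wake_interruption_s,
                                  seed = seed)
    di_rows <- list(); dcv <- numeric(0)
    pooled_i <- numeric(0); pooled_j <- numeric(0)
    cell_ci <- numeric(0); cell_q <- integer(0)
    n_cell_epochs <- 0L
    for (r in seq_len(nrow(seqs))) {
      if (seqs$excluded[r]) next
      period <- function(a, b) {
        iv <- interval_set(a, b)
        if (!is.null(exclude)) iv <- interval_subtract(iv, exclude)
        iv
      }
      pi_ <- period(seqs$i_start[r], seqs$i_end[r])
      pj_ <- period(seqs$j_start[r], seqs$j_end[r])
      pk_ <- period(seqs$k_start[r], seqs$k_end[r])
      if (iv_duration(pi_) == 0 || iv_duration(pj_) == 0 || iv_duration(pk_) == 0) {
        seqs$excluded[r] <- TRUE; seqs$reason[r] <- "period_fully_masked"
        next
      }
      fr_i <- period_rates(spikes, pi_)
      fr_j <- period_rates(spikes, pj_)
      fr_k <- period_rates(spikes, pk_)
      if (nonfiring_exclusion(fr_i[pc], fr_j[pc], nonfiring_threshold)) {
        seqs$excluded[r] <- TRUE; seqs$reason[r] <- "nonfiring_rule"
        next
      }
      q <- assign_quintiles(fr_i[pc], spikes$units$unit_id[pc])
      groups <- character(n_units(spikes))
      groups[pc] <- paste0("q", q)
      groups[!pc] <- "interneuron"
      ci <- change_index(fr_i, fr_j, groups)
      surr <- shuffle_surrogates(fr_i, fr_k,
                                 unit_ids = spikes$units$unit_id,
                                 cell_class = spikes$units$cell_class,
                                 n_shuffles = n_shuffles,
                                 seed = seed + 1000L + r)
      di <- deflection_index(ci, surr)
      di$sequence <- r
      di_rows[[length(di_rows) + 1L]] <- di
      dcv <- c(dcv, population_cv(fr_j[pc])$cv - population_cv(fr_i[pc])$cv)
      pooled_i <- c(pooled_i, fr_i[pc]); pooled_j <- c(pooled_j, fr_j[pc])
      ok <- !is.na(ci$cells$ci) & pc
      cell_ci <- c(cell_ci, ci$cells$ci[ok]); cell_q <- c(cell_q, q[ok[pc]])
      n_cell_epochs <- n_cell_epochs + sum(ok)
    }
    di_all <- if (length(di_rows)) do.call(rbind, di_rows) else NULL
    di_summary <- NULL
    if (!is.null(di_all)) {
      di_summary <- do.call(rbind, lapply(unique(di_all$group), function(g) {
        d <- di_all$di[di_all$group == g]
        tst <- report_tests(d, "signed_rank")
        data.frame(group = g, mean_di = mean(d), n_sequences = length(d),
                   p_signed_rank = tst$p, stringsAsFactors = FALSE)
      }))
    }
    out[[kind]] <- list(
      sequences = seqs,
      di_by_sequence = di_all,
      di_summary = di_summary,
      dcv = dcv,
      dcv_test = if (length(dcv) >= 2L) report_tests(dcv, "signed_rank") else NULL,
      ks_test = if (length(pooled_i) >= 5L)
        report_tests(pooled_i, "ks", values2 = pooled_j) else NULL,
      anova_quintile_ci = if (length(cell_ci) >= 10L)
        report_tests(cell_ci, "anova", groups = cell_q) else NULL,
      accounting = data.frame(
        n_sequences_extracted = nrow(seqs),
        n_sequences_analyzed = length(dcv),
        n_excluded_no_control = sum(seqs$reason == "no_control"),
        n_excluded_nonfiring = sum(seqs$reason == "nonfiring_rule"),
        n_excluded_other = sum(seqs$excluded) - sum(seqs$reason %in%
          c("no_control", "nonfiring_rule")),
        n_cell_epochs = n_cell_epochs
      )
    )
  }
  structure(c(out, list(config = list(
    kinds = kinds, min_nrem_s = min_nrem_s, min_rem_s = min_rem_s,
    nonfiring_threshold = nonfiring_threshold, n_shuffles = n_shuffles,
    seed = seed, same_bout = same_bout, max_gap_s = max_gap_s,
    excluded_time_s = if (is.null(exclude)) 0 else iv_duration(exclude)
  ))), class = "analysis_bundle")
}

#' Compare analyses under substate-exclusion variants
#'
#' Repeats [run_transition_analysis()] under each named exclusion set (e.g.
#' `list(intact = NULL, off = <OFF intervals>, off_low = <union>)`) and
#' returns the per-variant bundles plus a comparison table of the headline
#' metrics. Also verifies the structural fact that removing population
#' silence can only raise (or keep) a cell's NREM rate: per-cell NREM rates
#' under OFF exclusion are compared against the intact NREM rates.
#'
#' @param spikes A [spike_table].
#' @param h A [hypnogram].
#' @param exclusions Named list of `interval_set`s (or `NULL` for intact).
#' @param off Optional OFF `interval_set` used for the rate-monotonicity
#'   check; defaults to `exclusions$off` when present.
#' @param ... Passed to [run_transition_analysis()].
#' @return List: `variants` (named bundles), `comparison` (metric x variant
#'   table), `off_rate_check` (data.frame of per-cell intact vs OFF-excluded
#'   NREM rates with a `never_lower` attribute).
#' @export
run_exclusion_variants <- function(spikes, h, exclusions = list(intact = NULL),
                                   off = NULL, ...) {
  variants <- lapply(exclusions, function(ex)
    run_transition_analysis(spikes, h, exclude = ex, ...))
  rows <- list()
  for (v in names(variants)) {
    b <- variants[[v]]
    for (kind in setdiff(names(b), "config")) {
      el <- b[[kind]]
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, kind = kind,
        mean_dcv = if (length(el$dcv)) mean(el$dcv) else NA_real_,
        p_dcv = if (!is.null(el$dcv_test)) el$dcv_test$p else NA_real_,
        n_sequences = el$accounting$n_sequences_analyzed,
        stringsAsFactors = FALSE)
    }
  }
  off <- off %||% exclusions[["off"]]
  off_check <- NULL
  if (!is.null(off)) {
    nrem <- state_intervals(h, "NREM")
    intact <- period_rates(spikes, nrem)
    masked <- period_rates(spikes, exclusion_mask(nrem, off))
    off_check <- data.frame(unit_id = spikes$units$unit_id,
                            intact_hz = intact, off_excluded_hz = masked,
                            stringsAsFactors = FALSE, row.names = NULL)
    attr(off_check, "never_lower") <- all(masked >= intact - 1e-12)
  }
  list(variants = variants, comparison = do.call(rbind, rows),
       off_rate_check = off_check)
}
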