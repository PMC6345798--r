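#' Epochs of a hypnogram
#'
#' An epoch is one maximal contiguous interval of a single state. Externally
#' scored microarousal (`MA`) rows never form epochs; with `bridge_ma = TRUE`
#' (default) two NREM intervals separated only by an MA interval are fused
#' into one NREM epoch, so brief arousals do not split NREM.
#'
#' @param h A [hypnogram].
#' @param bridge_ma Fuse same-state epochs separated exactly by an MA interval.
#' @return data.frame with columns `index`, `state`, `start`, `end`,
#'   `duration`; `index` is the position in the session's epoch sequence.
#' @export
session_epochs <- function(h, bridge_ma = TRUE) {
  stopifnot(is_hypnogram(h))
  rows <- h[h$state %in% c("WAKE", "NREM", "REM"), , drop = FALSE]
  ma <- h[h$state == "MA", , drop = FALSE]
  state <- rows$state; start <- rows$start; end <- rows$end
  if (bridge_ma && nrow(ma) && length(state) > 1L) {
    i <- 1L
    while (i < length(state)) {
      gap_filled <- any(abs(ma$start - end[i]) < 1e-9 &
                        abs(ma$end - start[i + 1L]) < 1e-9)
      if (state[i] == state[i + 1L] && gap_filled) {
        end[i] <- end[i + 1L]
        state <- state[-(i + 1L)]; start <- start[-(i + 1L)]; end <- end[-(i + 1L)]
      } else i <- i + 1L
    }
  }
  data.frame(index = seq_along(state), state = state, start = start,
             end = end, duration = end - start,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Duration-filter epochs
#'
#' Only NREM epochs strictly longer than `min_nrem_s` and REM epochs strictly
#' longer than `min_rem_s` enter any analysis; all WAKE epochs are kept.
#' Failing epochs are invisible downstream: they neither break nor join
#' sequences, and adjacency is evaluated on the survivors.
#'
#' @param h A [hypnogram] or an epochs data.frame from [session_epochs()].
#' @param min_nrem_s Minimum NREM duration, s (strict `>`; default 150).
#' @param min_rem_s Minimum REM duration, s (strict `>`; default 100).
#' @param bridge_ma Passed to [session_epochs()] when `h` is a hypnogram.
#' @return Epochs data.frame (same columns as [session_epochs()]), original
#'   session indices retained.
#' @export
filter_epochs <- function(h, min_nrem_s = 150, min_rem_s = 100,
                          bridge_ma = TRUE) {
  ep <- if (is_hypnogram(h)) session_epochs(h, bridge_ma = bridge_ma) else h
  keep <- (ep$state == "WAKE") |
    (ep$state == "NREM" & ep$duration > min_nrem_s) |
    (ep$state == "REM" & ep$duration > min_rem_s)
  ep[keep, , drop = FALSE]
}

#' Split an epoch into three equal thirds
#'
#' The thirds are half-open, contiguous, and partition the epoch exactly
#' (duration conserved to machine precision by telescoping bounds).
#'
#' @param start,end Epoch bounds, s.
#' @return data.frame with columns `third` (1..3), `start`, `end`.
#' @export
epoch_thirds <- function(start, end) {
  stopifnot(end > start)
  d <- end - start
  b <- c(start, start + d / 3, start + 2 * d / 3, end)
  data.frame(third = 1:3, start = b[1:3], end = b[2:4])
}

third_interval <- function(start, end, third) {
  if (third == 0L) return(c(start, end))  # whole epoch
  th <- epoch_thirds(start, end)
  c(th$start[third], th$end[third])
}

seq_kinds <- c("NREM_REM", "REM_NREM", "WAKE_NREM", "NREM_WAKE", "REM_WAKE",
               "NREM_REM_NREM", "REM_NREM_REM", "SLEEP_first_last_NREM",
               "WAKE_SLEEP_WAKE", "within_NREM", "within_REM")

# Sleep bouts over a filtered epoch table: maximal runs of NREM/REM epochs in
# which any interposed WAKE epoch is <= max_wake_interruption_s. Returns an
# integer bout id per epoch row (NA for WAKE epochs not inside a bout).
sleep_bouts <- function(epochs, max_wake_interruption_s = 60) {
  n <- nrow(epochs)
  bout <- rep(NA_integer_, n)
  cur <- 0L
  open <- FALSE
  for (r in seq_len(n)) {
    st <- epochs$state[r]
    if (st %in% c("NREM", "REM")) {
      if (!open) { cur <- cur + 1L; open <- TRUE }
      bout[r] <- cur
    } else {  # WAKE
      if (open && epochs$duration[r] <= max_wake_interruption_s) {
        # short interruption: bout continues if sleep follows
        nxt <- if (r < n) epochs$state[r + 1L] else "WAKE"
        if (nxt %in% c("NREM", "REM")) bout[r] <- cur else open <- FALSE
      } else open <- FALSE
    }
  }
  bout
}

blank_seq_row <- function() {
  data.frame(kind = character(0), e_i = integer(0), e_j = integer(0),
             e_k = integer(0), i_start = numeric(0), i_end = numeric(0),
             j_start = numeric(0), j_end = numeric(0), k_start = numeric(0),
             k_end = numeric(0), i_third = integer(0),
             control_state = character(0), excluded = logical(0),
             reason = character(0), stringsAsFactors = FALSE)
}

seq_row <- function(kind, e_i, e_j, e_k = NA_integer_, pi, pj, pk = c(NA_real_, NA_real_),
                    i_third, control_state, excluded = FALSE, reason = "") {
  data.frame(kind = kind, e_i = e_i, e_j = e_j, e_k = e_k,
             i_start = pi[1], i_end = pi[2], j_start = pj[1], j_end = pj[2],
             k_start = pk[1], k_end = pk[2], i_third = i_third,
             control_state = control_state, excluded = excluded,
             reason = reason, stringsAsFactors = FALSE)
}

#' Extract state sequences from filtered epochs
#'
#' Matches a pattern of consecutive surviving epochs and derives the two
#' analysis periods. For state-pair transitions, period i is the last third
#' of the first epoch and period j the first third of the second. Within-state
#' kinds compare the first vs last third of one epoch. Triplets
#' (`NREM_REM_NREM`, `REM_NREM_REM`) carry their own control period k: the
#' same third of the far epoch of the same state. `SLEEP_first_last_NREM`
#' compares the first and last whole NREM epochs of a continuous sleep bout;
#' `WAKE_SLEEP_WAKE` compares the last minute of the wake epoch before a bout
#' with the first minute of the wake epoch after it.
#'
#' @param epochs Filtered epochs data.frame from [filter_epochs()].
#' @param kind One of `"NREM_REM"`, `"REM_NREM"`, `"WAKE_NREM"`, `"NREM_WAKE"`,
#'   `"REM_WAKE"`, `"NREM_REM_NREM"`, `"REM_NREM_REM"`,
#'   `"SLEEP_first_last_NREM"`, `"WAKE_SLEEP_WAKE"`, `"within_NREM"`,
#'   `"within_REM"`.
#' @param max_gap_s Maximum hypnogram gap, s, allowed between consecutive
#'   epochs of a sequence (gaps include epochs removed by duration filters).
#' @param wake_period_s Length of the wake analysis periods, s (default 60).
#' @param max_wake_interruption_s WAKE epochs up to this length, s, do not
#'   terminate a sleep bout.
#' @return A sequence table: one row per match, with period bounds
#'   (`i_start`..`k_end`), parent epoch indices (`e_i`, `e_j`, `e_k`), the
#'   third-position of period i (`i_third`; 0 = whole epoch), the state a
#'   control period must come from, and an exclusion flag + reason. Control
#'   bounds `k_*` are `NA` until filled by [select_control_period()], except
#'   for triplet kinds where k is structural.
#' @export
extract_sequences <- function(epochs, kind, max_gap_s = Inf,
                              wake_period_s = 60,
                              max_wake_interruption_s = 60) {
  kind <- match.arg(kind, seq_kinds)
  out <- blank_seq_row()
  n <- nrow(epochs)
  gap_ok <- function(r1, r2) (epochs$start[r2] - epochs$end[r1]) <= max_gap_s
  lastthird <- function(r) third_interval(epochs$start[r], epochs$end[r], 3L)
  firstthird <- function(r) third_interval(epochs$start[r], epochs$end[r], 1L)

  if (kind %in% c("NREM_REM", "REM_NREM", "WAKE_NREM", "NREM_WAKE", "REM_WAKE")) {
    ab <- strsplit(kind, "_", fixed = TRUE)[[1L]]
    for (r in seq_len(max(0L, n - 1L))) {
      if (epochs$state[r] == ab[1] && epochs$state[r + 1L] == ab[2] &&
          gap_ok(r, r + 1L)) {
        out <- rbind(out, seq_row(kind, epochs$index[r], epochs$index[r + 1L],
                                  pi = lastthird(r), pj = firstthird(r + 1L),
                                  i_third = 3L, control_state = ab[1]))
      }
    }
  } else if (kind %in% c("NREM_REM_NREM", "REM_NREM_REM")) {
    sts <- strsplit(kind, "_", fixed = TRUE)[[1L]]
    for (r in seq_len(max(0L, n - 2L))) {
      if (all(epochs$state[r + 0:2] == sts) && gap_ok(r, r + 1L) &&
          gap_ok(r + 1L, r + 2L)) {
        out <- rbind(out, seq_row(kind, epochs$index[r], epochs$index[r + 1L],
                                  epochs$index[r + 2L],
                                  pi = lastthird(r), pj = firstthird(r + 1L),
                                  pk = lastthird(r + 2L),
                                  i_third = 3L, control_state = sts[1]))
      }
    }
  } else if (kind %in% c("within_NREM", "within_REM")) {
    st <- sub("within_", "", kind)
    for (r in seq_len(n)) {
      if (epochs$state[r] == st) {
        out <- rbind(out, seq_row(kind, epochs$index[r], epochs$index[r],
                                  pi = firstthird(r), pj = lastthird(r),
                                  i_third = 1L, control_state = st))
      }
    }
  } else if (kind == "SLEEP_first_last_NREM") {
    bout <- sleep_bouts(epochs, max_wake_interruption_s)
    for (b in unique(bout[!is.na(bout)])) {
      rows <- which(bout == b & epochs$state == "NREM")
      if (length(rows) >= 2L) {
        r1 <- rows[1L]; r2 <- rows[length(rows)]
        out <- rbind(out, seq_row(kind, epochs$index[r1], epochs$index[r2],
                                  pi = c(epochs$start[r1], epochs$end[r1]),
                                  pj = c(epochs$start[r2], epochs$end[r2]),
                                  i_third = 0L, control_state = "NREM"))
      }
    }
  } else if (kind == "WAKE_SLEEP_WAKE") {
    bout <- sleep_bouts(epochs, max_wake_interruption_s)
    for (b in unique(bout[!is.na(bout)])) {
      rows <- which(bout == b)
      r1 <- rows[1L]; r2 <- rows[length(rows)]
      wa <- r1 - 1L; wb <- r2 + 1L
      if (wa >= 1L && wb <= n &&
          epochs$state[wa] == "WAKE" && epochs$state[wb] == "WAKE" &&
          is.na(bout[wa]) && is.na(bout[wb]) &&
          gap_ok(wa, r1) && gap_ok(r2, wb)) {
        short <- epochs$duration[wa] < wake_period_s ||
                 epochs$duration[wb] < wake_period_s
        out <- rbind(out, seq_row(
          kind, epochs$index[wa], epochs$index[wb],
          pi = c(epochs$end[wa] - wake_period_s, epochs$end[wa]),
          pj = c(epochs$start[wb], epochs$start[wb] + wake_period_s),
          i_third = NA_integer_, control_state = "WAKE",
          excluded = short,
          reason = if (short) "wake_epoch_shorter_than_period" else ""))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Fill control periods for the shuffle null
#'
#' For sequences whose period i lives in NREM or REM, the control period k is
#' the corresponding sub-interval (same third position as period i) of the
#' nearest adjacent same-state epoch passing the duration filters; when
#' `same_bout = TRUE` candidates are restricted to the same sleep bout. For
#' wake-anchored sequences, k is a uniformly random sub-interval of the same
#' wake epoch ([select_wake_control()]). Sequences with no admissible control
#' are flagged `excluded` with reason `"no_control"` -- never an error.
#'
#' @param seqs Sequence table from [extract_sequences()].
#' @param epochs The same filtered epochs table used for extraction.
#' @param same_bout Restrict NREM/REM controls to the same sleep bout.
#' @param max_wake_interruption_s Sleep-bout definition, as in extraction.
#' @param wake_period_s Wake control length, s.
#' @param seed RNG seed for wake-control draws (reproducible).
#' @return The sequence table with `k_start`/`k_end` filled where possible.
#' @export
select_control_period <- function(seqs, epochs, same_bout = TRUE,
                                  max_wake_interruption_s = 60,
                                  wake_period_s = 60, seed = NULL) {
  bout <- sleep_bouts(epochs, max_wake_interruption_s)
  with_seed(seed, {
    for (r in seq_len(nrow(seqs))) {
      if (seqs$excluded[r] || !is.na(seqs$k_start[r])) next
      cs <- seqs$control_state[r]
      if (cs == "WAKE") {
        row <- which(epochs$index == seqs$e_i[r])
        k <- select_wake_control(epochs$start[row], epochs$end[row],
                                 period_i = c(seqs$i_start[r], seqs$i_end[r]),
                                 duration_s = wake_period_s)
        if (is.null(k)) {
          seqs$excluded[r] <- TRUE; seqs$reason[r] <- "wake_epoch_too_short"
        } else { seqs$k_start[r] <- k[1]; seqs$k_end[r] <- k[2] }
        next
      }
      parent <- which(epochs$index == seqs$e_i[r])
      cand <- which(epochs$state == cs & seq_len(nrow(epochs)) != parent)
      if (same_bout && !is.na(bout[parent]))
        cand <- cand[!is.na(bout[cand]) & bout[cand] == bout[parent]]
      if (!length(cand)) {
        seqs$excluded[r] <- TRUE; seqs$reason[r] <- "no_control"
        next
      }
      dist <- abs(epochs$start[cand] - epochs$start[parent])
      pick <- cand[which.min(dist)]
      k <- third_interval(epochs$start[pick], epochs$end[pick], seqs$i_third[r])
      seqs$k_start[r] <- k[1]; seqs$k_end[r] <- k[2]
    }
    seqs
  })
}

#' Random wake control period
#'
#' A uniformly random `duration_s` sub-interval of the wake epoch, drawn from
#' the current RNG stream. Up to `max_tries` rejection draws avoid returning
#' an interval identical to `period_i`; when the epoch is exactly
#' `duration_s` long the unique interval (the epoch itself) is returned.
#'
#' @param start,end Wake epoch bounds, s.
#' @param period_i Optional analysis period to avoid duplicating.
#' @param duration_s Control length, s (default 60).
#' @param max_tries Rejection bound before allowing overlap with `period_i`.
#' @return Numeric `(start, end)` of the control, or `NULL` if the epoch is
#'   shorter than `duration_s`.
#' @export
select_wake_control <- function(start, end, period_i = NULL, duration_s = 60,
                                max_tries = 20L) {
  if (end - start < duration_s) return(NULL)
  draw <- function() {
    s <- stats::runif(1L, start, end - duration_s)
    c(s, s + duration_s)
  }
  k <- draw()
  if (!is.null(period_i) && (end - start) > duration_s) {
    tries <- 0L
    while (tries < max_tries && isTRUE(all(abs(k - period_i) < 1e-9))) {
      k <- draw(); tries <- tries + 1L
    }
  }
  k
}

#' Sequence-level non-firing exclusion
#'
#' A sequence is dropped when more than `threshold` (strictly greater) of its
#' cells are silent in period i or in period j: the lowest quintile's change
#' index is not meaningful when a fifth of the population contributes zeros.
#'
#' @param fr_i,fr_j Aligned per-cell mean rates, Hz, in periods i and j.
#' @param threshold Silent fraction above which the sequence is excluded.
#' @return `TRUE` if the sequence should be excluded.
#' @export
nonfiring_exclusion <- function(fr_i, fr_j, threshold = 0.20) {
  if (length(fr_i) == 0L || length(fr_i) != length(fr_j))
    stop("fr_i and fr_j must be non-empty and aligned")
  mean(fr_i == 0) > threshold || mean(fr_j == 0) > threshold
}
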