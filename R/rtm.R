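#' Change index between two periods
#'
#' The cell-level change index is `(FR_i - FR_j) / (FR_i + FR_j)`: bounded in
#' `[-1, 1]`, scale-free, and antisymmetric in its arguments (positive values
#' mean a rate *decrease* from i to j). The group-level CI of a quintile (or
#' of the interneuron group) is the CI of the group's mean rates,
#' `(mean FR_i - mean FR_j) / (mean FR_i + mean FR_j)`. Cells silent in both
#' periods have no defined cell-level CI and are excluded (with counts
#' reported); under the group-mean formula they contribute zero to both sums,
#' so the group CI is unaffected.
#'
#' @param fr_i,fr_j Aligned per-cell mean rates, Hz (>= 0).
#' @param groups Group label per cell (e.g. `"q1"`..`"q5"` from
#'   [assign_quintiles()], `"interneuron"`). A single label is recycled.
#' @return Object of class `ci_result`: list with `cells` (per-cell
#'   data.frame: `group`, `fr_i`, `fr_j`, `ci`) and `groups` (per-group
#'   data.frame: `group`, `ci`, `mean_ci_cells`, `n_cells`, `n_excluded`).
#' @export
change_index <- function(fr_i, fr_j, groups = "all") {
  n <- length(fr_i)
  if (n == 0L || length(fr_j) != n) stop("fr_i and fr_j must be non-empty and aligned")
  if (any(fr_i < 0) || any(fr_j < 0)) stop("rates must be >= 0")
  groups <- rep_len(as.character(groups), n)
  both_zero <- fr_i == 0 & fr_j == 0
  if (all(both_zero)) stop("all cells silent in both periods")
  ci <- ifelse(both_zero, NA_real_, (fr_i - fr_j) / (fr_i + fr_j))
  glev <- unique(groups)
  gtab <- do.call(rbind, lapply(glev, function(g) {
    sel <- groups == g
    mi <- mean(fr_i[sel]); mj <- mean(fr_j[sel])
    data.frame(group = g,
               ci = if (mi + mj > 0) (mi - mj) / (mi + mj) else NA_real_,
               mean_ci_cells = mean(ci[sel], na.rm = TRUE),
               n_cells = sum(sel & !both_zero),
               n_excluded = sum(sel & both_zero),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    cells = data.frame(group = groups, fr_i = fr_i, fr_j = fr_j, ci = ci,
                       stringsAsFactors = FALSE),
    groups = gtab
  ), class = "ci_result")
}

#' Log firing-rate change
#'
#' `log10(FR_j) - log10(FR_i)` per cell, the classical alternative to the
#' change index. It is singular when either rate approaches zero, which is
#' why the bounded CI is preferred for sparsely firing populations; cells
#' with a zero rate in either period are excluded (count reported).
#'
#' @param fr_i,fr_j Aligned per-cell rates, Hz.
#' @return List: `dlog` (per-cell, `NA` where excluded), `n_excluded`.
#' @export
delta_log_fr <- function(fr_i, fr_j) {
  stopifnot(length(fr_i) == length(fr_j))
  ok <- fr_i > 0 & fr_j > 0
  dlog <- ifelse(ok, log10(fr_j) - log10(fr_i), NA_real_)
  list(dlog = dlog, n_excluded = sum(!ok))
}

#' Shuffle surrogates for the RTM null
#'
#' The null hypothesis is that changes across states are no different from
#' changes within a state, allowing for regression to the mean. Each of the
#' `n_shuffles` surrogates independently flips, per cell with probability
#' 1/2, the rates of period i and the same-state control period k; quintiles
#' are then re-derived from the post-flip first slot, and the group CI is
#' computed between the two slots -- so every surrogate CI runs either
#' forward (i to k) or backward (k to i) in time within the same state, and
#' its distribution captures the RTM bias that rank-selection induces.
#'
#' @param fr_i,fr_k Aligned per-cell rates, Hz, for period i and the control
#'   period k.
#' @param unit_ids Unit ids for deterministic tie-breaks (default
#'   `names(fr_i)` or index order).
#' @param cell_class Optional per-cell class; `"interneuron"` cells form one
#'   fixed group and are never quintiled.
#' @param n_groups Number of rank groups for principal cells (default 5).
#' @param n_shuffles Number of surrogates (default 2000).
#' @param seed RNG seed; identical seeds give bit-identical surrogates.
#' @param refit_groups Re-derive quintiles inside each shuffle from the
#'   post-flip first slot (default, the primary analysis). `FALSE` freezes
#'   membership at the observed assignment -- a sensitivity variant.
#' @return Object of class `surrogate_distribution`: list with `values`
#'   (`n_shuffles` x groups matrix of surrogate group CIs), `n_shuffles`,
#'   `seed`, `refit_groups`.
#' @export
shuffle_surrogates <- function(fr_i, fr_k, unit_ids = names(fr_i),
                               cell_class = NULL, n_groups = 5L,
                               n_shuffles = 2000L, seed = NULL,
                               refit_groups = TRUE) {
  n <- length(fr_i)
  if (n == 0L || length(fr_k) != n)
    stop("fr_i and fr_k must be non-empty and aligned (is the control period missing?)")
  if (is.null(unit_ids)) unit_ids <- as.character(seq_len(n))
  if (is.null(cell_class)) cell_class <- rep("principal", n)
  pc <- cell_class == "principal"
  # order principal cells by unit id so that a stable sort on rates breaks
  # ties by ascending unit id, matching assign_quintiles()
  ord_id <- order(unit_ids[pc])
  pi_ <- fr_i[pc][ord_id]; pk_ <- fr_k[pc][ord_id]
  np <- length(pi_)
  if (np < n_groups) stop(sprintf("need at least %d principal cells", n_groups))
  qt <- as.integer(ceiling(n_groups * seq_len(np) / np))
  bnd <- cumsum(tabulate(qt, n_groups))
  o_frozen <- if (!refit_groups) {
    frozen <- assign_quintiles(pi_, unit_ids[pc][ord_id], n_groups)
    order(frozen, unit_ids[pc][ord_id])
  } else NULL
  has_int <- any(!pc)
  ii <- fr_i[!pc]; ik <- fr_k[!pc]
  gnames <- c(paste0("q", seq_len(n_groups)), if (has_int) "interneuron")
  vals <- matrix(NA_real_, n_shuffles, length(gnames),
                 dimnames = list(NULL, gnames))
  with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      flip <- stats::runif(n) < 0.5
      fp <- flip[pc][ord_id]
      si <- pi_; si[fp] <- pk_[fp]
      sk <- pk_; sk[fp] <- pi_[fp]
      o <- if (refit_groups) order(si) else o_frozen
      csi <- cumsum(si[o]); csk <- cumsum(sk[o])
      sum_i <- diff(c(0, csi[bnd])); sum_k <- diff(c(0, csk[bnd]))
      vals[s, seq_len(n_groups)] <- (sum_i - sum_k) / (sum_i + sum_k)
      if (has_int) {
        fi <- flip[!pc]
        mi <- mean(ifelse(fi, ik, ii)); mk <- mean(ifelse(fi, ii, ik))
        vals[s, n_groups + 1L] <- (mi - mk) / (mi + mk)
      }
    }
  })
  structure(list(values = vals, n_shuffles = n_shuffles, seed = seed,
                 refit_groups = refit_groups,
                 scheme = "per-cell i/k flip, p = 1/2"),
            class = "surrogate_distribution")
}

#' Deflection index: RTM-corrected change
#'
#' DI = observed group CI minus the mean of the surrogate group CIs; the 95%
#' band is the (2.5, 97.5) percentile interval of the surrogates, and the
#' empirical two-tailed p-value is
#' `(1 + #{|s - mean| >= |observed - mean|}) / (n_shuffles + 1)`.
#' Under a pure-noise population the DI of every quintile is statistically
#' zero even though the raw CI of extreme quintiles is biased by RTM.
#'
#' @param ci A `ci_result` from [change_index()].
#' @param surr A `surrogate_distribution` from [shuffle_surrogates()] with
#'   matching group labels.
#' @return data.frame of class `di_result`: per group `observed_ci`,
#'   `surrogate_mean`, `di`, `band_lo`, `band_hi`, `p`, `n_cells`,
#'   `n_shuffles`.
#' @export
deflection_index <- function(ci, surr) {
  stopifnot(inherits(ci, "ci_result"), inherits(surr, "surrogate_distribution"))
  g <- intersect(ci$groups$group, colnames(surr$values))
  if (!length(g)) stop("no common groups between observed CI and surrogates")
  out <- do.call(rbind, lapply(g, function(gr) {
    obs <- ci$groups$ci[ci$groups$group == gr]
    s <- surr$values[, gr]
    m <- mean(s)
    qs <- stats::quantile(s, c(0.025, 0.975), names = FALSE, type = 7)
    p <- (1 + sum(abs(s - m) >= abs(obs - m))) / (length(s) + 1)
    data.frame(group = gr, observed_ci = obs, surrogate_mean = m,
               di = obs - m, band_lo = qs[1], band_hi = qs[2], p = p,
               n_cells = ci$groups$n_cells[ci$groups$group == gr],
               n_shuffles = length(s), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("di_result", "data.frame")
  out
}

#' Standard-test wrappers for reporting
#'
#' The three tests used throughout the reports: a paired Wilcoxon signed-rank
#' test on per-sequence deltas (e.g. delta-CV), a two-sample
#' Kolmogorov-Smirnov test on pooled per-cell rate distributions, and a
#' one-way ANOVA on per-cell changes across the five quintiles.
#'
#' @param values Numeric vector: per-sequence deltas (`signed_rank`), first
#'   sample (`ks`), or per-cell values (`anova`).
#' @param design `"signed_rank"`, `"ks"` or `"anova"`.
#' @param values2 Second sample for `ks`.
#' @param groups Group labels aligned with `values` for `anova`.
#' @param min_n Minimum sample size; below it the result is flagged and no p
#'   is reported.
#' @return data.frame: `design`, `statistic`, `p`, `n`, `flagged`.
#' @export
report_tests <- function(values, design = c("signed_rank", "ks", "anova"),
                         values2 = NULL, groups = NULL, min_n = 5L) {
  design <- match.arg(design)
  flagged <- FALSE; stat <- NA_real_; p <- NA_real_
  n <- length(values)
  if (design == "signed_rank") {
    if (n < min_n || all(values == 0)) flagged <- n < min_n
    if (!flagged) {
      wt <- suppressWarnings(stats::wilcox.test(values, mu = 0, exact = FALSE))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    if (all(values == 0)) { stat <- 0; p <- 1; flagged <- FALSE }
  } else if (design == "ks") {
    if (is.null(values2)) stop("ks design needs values2")
    if (n < min_n || length(values2) < min_n) flagged <- TRUE
    else {
      kt <- suppressWarnings(stats::ks.test(values, values2))
      stat <- unname(kt$statistic); p <- kt$p.value
    }
  } else {
    if (is.null(groups)) stop("anova design needs groups")
    ok <- !is.na(values)
    values <- values[ok]; groups <- factor(groups[ok]); n <- length(values)
    if (n < min_n || nlevels(groups) < 2L) flagged <- TRUE
    else {
      fit <- stats::aov(values ~ groups)
      tab <- summary(fit)[[1L]]
      stat <- tab[["F value"]][1L]; p <- tab[["Pr(>F)"]][1L]
    }
  }
  data.frame(design = design, statistic = stat, p = p, n = n,
             flagged = flagged, stringsAsFactors = FALSE)
}
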