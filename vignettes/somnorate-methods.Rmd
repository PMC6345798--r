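---
title: "Quantifying sleep-state firing-rate dynamics with RTM-corrected change indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sleep-state firing-rate dynamics with RTM-corrected change indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnorate)
```

## The problem

Cortical and hippocampal neurons fire at rates spanning three orders of
magnitude, roughly log-normally distributed across a population. Sleep
states reshape that distribution: transitions into REM widen it (low-firing
cells drop, high-firing cells hold or gain) while NREM narrows and
homogenizes it. Measuring such rank-dependent changes is statistically
treacherous: if cells are grouped by their rate in one period and tracked
into another, regression to the mean (RTM) alone produces apparent
rate-dependent changes — the lowest-firing group appears to rise and the
highest to fall even when nothing happened. `somnorate` implements the
analysis toolchain for this problem: interval algebra over hypnograms,
epoch filtering and sequence extraction, quintile-resolved rate dynamics,
the population coefficient of variation (CV), and a shuffle-based
*deflection index* that removes the RTM bias, together with detectors for
three NREM substates (OFF, microarousal, LOW) and a synthetic-session
generator so every stage can be validated against planted ground truth.

## Core statistics

**Change index.** For per-cell mean rates $FR_i$, $FR_j$ over two periods,
the group (quintile or interneuron) change index is

$$CI = \frac{\overline{FR_i} - \overline{FR_j}}{\overline{FR_i} + \overline{FR_j}},$$

where the bar denotes the mean over the group's cells. It is bounded in
$[-1, 1]$, scale-free, antisymmetric, and — unlike $\Delta\log(FR)$ — finite
when cells fall silent. Positive values indicate a rate *decrease* from
$i$ to $j$. A per-cell CI is also computed (used for the across-quintile
ANOVA); the group statistic, however, is the CI of group means, not the
mean of per-cell CIs, so occasional cells silent in both periods cannot
distort it (they add zero to both sums and are reported as excluded).

**Quintiles.** Principal cells are ranked ascending by rate; the cell of
1-based rank $r$ among $n$ joins quintile $\lceil 5r/n \rceil$, giving
deterministic groups whose sizes differ by at most one. Ties (including
multiple silent cells) break by unit id so re-runs are reproducible.
Interneurons are never quintiled; they form one separate group. Two sorting
modes exist because they answer different questions: ranking on the *whole
window* avoids RTM for descriptive traces, whereas ranking on *epoch i*
(used by the CI/DI analysis) deliberately exposes RTM so that the shuffle
correction can remove it.

**Deflection index.** The null hypothesis is that changes across states are
no different from changes within a state, allowing for RTM. Each sequence
provides a control period $k$ of the same state as $i$ (the matching third
of the nearest adjacent same-state epoch inside the same sleep bout, or a
random 1-minute window of the same wake epoch for wake-anchored
comparisons). Each of the 2000 surrogates flips $FR_i$ and $FR_k$
independently per cell with probability 1/2, re-derives quintiles from the
post-flip first slot, and computes the group CI *between the two slots* —
every surrogate change therefore runs forward or backward in time within
one state and ends or originates in epoch $i$, and its distribution
captures exactly the RTM that rank-selection induces. Then

$$DI = CI_{\text{observed}} - \overline{CI}_{\text{surrogate}},$$

with a 95% percentile band and a two-tailed empirical p-value
$(1 + \#\{|s - \bar s| \ge |CI_{obs} - \bar s|\})/(n_{\text{shuffles}} + 1)$.
A design consequence worth stating: when $FR_i = FR_k$ exactly, every
surrogate CI is zero and the DI equals the observed CI — with no
within-state variability, the whole across-state change stands as
deflection. A fixed-membership variant (`refit_groups = FALSE`) is
available for sensitivity analysis.

**CV.** Population diversity is tracked as the coefficient of variation of
principal-cell rates (sample SD over mean). ΔCV per sequence (period j
minus period i) is tested across sequences with a Wilcoxon signed-rank
test; rate distributions are compared with a two-sample Kolmogorov–Smirnov
test; quintile gradients with a one-way ANOVA.

## Filtering rules and conventions

- All times are double-precision seconds; all intervals half-open
  $[a, b)$; a spike at $t$ belongs to $[a,b)$ iff $a \le t < b$, so touching
  intervals never double-count.
- Only NREM epochs strictly longer than 150 s and REM epochs strictly
  longer than 100 s enter any analysis; failing epochs are invisible —
  they neither break nor join sequences.
- A sequence is excluded when more than 20% (strict) of cells are silent
  in period $i$ or $j$: the lowest quintile's CI is meaningless when a
  fifth of the population contributes zeros.
- Transition periods default to the last third of the first epoch versus
  the first third of the second; within-state comparisons use first versus
  last third of one epoch; wake-anchored comparisons use 1-minute windows.
- "Continuous sleep" (for sleep-bout and wake–sleep–wake sequences) is a
  maximal run of NREM/REM epochs in which any interposed WAKE epoch lasts
  at most 60 s (configurable); the bound is a convention of this package.
- Control epochs are restricted to the same sleep bout by default
  (overridable), choosing the nearest same-state epoch in either direction.

## Substate detectors

**OFF states** are gaps in the pooled population spike train strictly
longer than 75 ms, inside one NREM interval, with both flanking spikes in
that interval — boundary gaps are not emitted because they conflate
state-transition silence with OFF states. The emitted interval is the open
gap; its left edge is nudged 1 ns past the flanking spike so that excluding
OFF time can never remove a spike, which guarantees the structural fact
that OFF exclusion never lowers any unit's NREM rate. With fewer than 10
units a warning notes that population silence is weakly informative.

**Microarousals** are maximal supra-threshold runs of the EMG-power trace
within NREM whose duration lies strictly between 0.1 and 40 s. The
per-session threshold is the NREM mean plus 0.5 SD by default, or the
valley of a bimodal EMG histogram; the trace can optionally be smoothed
first (off by default). EMG statistics are computed over NREM samples only.

**LOW states** are maximal sub-threshold runs of broadband (0.625–50 Hz)
band-power within NREM; the trace is expected as sliding 1-s windows at
0.1-s steps (computing it from raw LFP is out of scope). The threshold is
the valley of a kernel-smoothed histogram of log10 power within NREM (100
bins, Gaussian bandwidth 3 bins, deterministic) between its two largest
modes; a unimodal histogram falls back to a percentile threshold (10th by
default) with a warning. This valley rule is this package's documented
procedure; upstream implementations differ in detail.

Exclusion masks subtract the *union* of the chosen substates from NREM, so
overlapping substates are removed exactly once and time is conserved to
1 ns.

## The simulators

`simulate_population()` draws 5000 per-cell baselines from a log-normal
matched to hippocampal pyramidal cells in NREM (linear mean 0.59 Hz, SD
0.84 Hz, converted by exact moment matching), builds three epochs $i, j, k$,
and perturbs epoch $j$ by nothing, +0.05 Hz, or ×1.1. Noise is
rate-proportional: $FR = b(1 + \varepsilon)$ with
$\varepsilon \sim N(0, 0.35)$. We read the printed noise magnitude as the
*relative* SD of the proportional noise, for two reasons: it keeps zero
truncation negligible (≈0.2% of rate values clipped, reported by the
generator), and it is the calibration under which the multiplicative
scenario's deflection index is uniform across quintiles at the closed-form
value $(1 - 1.1)/(1 + 1.1) = -1/21$ — the diagnostic behaviour that
motivates the DI. Under the alternative reading (absolute 0.35 Hz at the
population mean, i.e. relative SD ≈ 0.59), truncation at zero clips ~4.6%
of values and systematically attenuates the lowest quintile's DI to ≈
−0.012, destroying that uniformity. Negative rates are truncated at zero
(the clipped fraction is monitored); epoch $k$ always carries the
unchanged baseline, since it plays the role of a same-state control.

`simulate_session()` generates a full synthetic recording: a hypnogram with
a WAKE/(NREM–REM)×k/WAKE architecture and log-normal epoch durations
(defaults NREM 600 s, REM 180 s, WAKE 900 s — testing conventions, not
measured values), inhomogeneous-Poisson spike trains with intensity =
baseline × state modulation × substate gating, planted OFF (intensity 0),
LOW (configurable gain, default 0.3) and microarousal intervals inside
NREM, an EMG trace elevated inside planted MAs, a band-power trace lowered
inside planted LOWs, and a complete ground-truth ledger. The default REM
modulation (0.6, 0.8, 0.9, 1.0, 1.1 across quintiles of the baseline)
mimics the qualitative REM-widening / NREM-narrowing phenomenon; planted
MA and LOW bounds snap to the trace grid so the detectors can be tested
for exact recovery. What the generator does *not* emulate: spike-sorting
artifacts, bursting and refractory structure, within-epoch rate drift,
correlated population dynamics, or real scoring noise in the hypnogram —
so passing tests validate the statistical machinery, not the biology of
any particular dataset.

## Numerical choices and edge cases

- Quintile re-derivation inside each shuffle uses a stable radix sort with
  unit-id tie-breaks, so surrogates are bit-reproducible under a seed.
- Group CI sums cancel group sizes, so the per-shuffle statistic is a
  cumulative-sum difference over the sorted slot — the 2000-shuffle run on
  5000 cells takes about two seconds.
- Empirical p-values use the +1-smoothed two-tailed estimator; the 95%
  bands are percentile intervals (type-7 quantiles).
- Bins partially covered by an exclusion mask are occupancy-corrected and
  kept while at least 10% covered (configurable); fully masked bins are
  reported missing, never zero.
- Degenerate inputs are contracts, not crashes: empty interval algebra
  results are valid; a constant trace falls back from valley to percentile
  thresholding with a warning; sequences without an admissible control are
  flagged excluded rather than erroring.

## Validation design and problem sizes

The test suite validates each stage against independent oracles: interval
algebra against a 1-ms grid membership oracle; spike counting against a
brute-force loop; Monte-Carlo surrogates against exhaustive enumeration of
all $2^n$ flip patterns for small populations; the simulators against
closed forms (log-normal moments, per-cell CI of a ×1.1 change, the
additive CI $-0.05/(2FR + 0.05)$). Scenario-level checks run the full
5000-cell, 2000-shuffle configuration; calibration claims (band exceedance
≈ 5% under the no-change model, planted ΔCV recovery) use 100 seeded
replicates, with session replicates sized at 50 principal cells and 24
NREM–REM cycles — large enough for ≥ 20 sequences per replicate and a
well-powered signed-rank test, small enough to keep the whole suite
desk-scale. The additive-gradient check averages DI over 12 replicate
populations because the q4–q5 gap (≈ 0.02) is comparable to single-run
sampling noise; the averaged gradient is the stable signature of the
closed form.

## Known limitations

- Cell-epochs are treated as independent units, as in the source analysis
  tradition; no mixed-effects modelling of the cell × epoch dependence.
- Multiple-comparison handling is reporting-only (raw p-values with group
  counts); nothing is enforced.
- The LOW/MA threshold procedures are deterministic stand-ins for
  session-tuned upstream practice; on real data the thresholds deserve
  inspection.
- WAKE→REM transitions are excluded as a sequence kind (rare in rodent
  sleep architecture and undefined in the analysis design).
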