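test_that("sliding rates recover regular, silent, and Poisson trains", {
  rm <- sliding_rates(regular_unit(10, 300), c(0, 300))
  expect_true(all(abs(rm$rates - 10) <= 0.2))
  expect_equal(rm$bin_centers_s[1], 30)

  silent <- spike_table(list(s = numeric(0)), cell_class = "principal")
  expect_true(all(sliding_rates(silent, c(0, 300))$rates == 0))

  set.seed(9)
  tr <- sort(runif(rpois(1, 5 * 600), 0, 600))
  pois <- spike_table(list(p = tr), cell_class = "principal")
  rmp <- sliding_rates(pois, c(0, 600))
  # grand mean of window rates within 3 SE of the true 5 Hz
  se <- sqrt(5 * 600) / 600
  expect_lt(abs(mean(rmp$rates) - 5), 3 * se * 2)  # windows overlap; be loose
})

test_that("time-normalized bins partition the epoch and respect masks", {
  st <- regular_unit(10, 300)
  rm <- time_normalized_rates(st, c(0, 300), 30)
  expect_equal(ncol(rm$rates), 30L)
  expect_equal(rm$occupancy_s, rep(10, 30))  # 300 s / 30 bins = 10 s

  # a single spike in bin 7 of 10 with 12-s bins: that bin 1/12 Hz, rest 0
  one <- spike_table(list(u = 77), cell_class = "principal")
  rm1 <- time_normalized_rates(one, c(0, 120), 10)
  expect_equal(unname(rm1$rates[1, 7]), 1 / 12)
  expect_equal(sum(rm1$rates[1, -7]), 0)

  # bins fully removed by the mask are NA, not zero
  mask <- interval_set(60, 120)
  rm2 <- time_normalized_rates(one, c(0, 120), 10, mask = mask)
  expect_true(all(is.na(rm2$rates[1, 1:5])))
  expect_equal(unname(rm2$rates[1, 7]), 1 / 12)
})

test_that("rates on masked NREM equal counts over the mask (grid consistency)", {
  set.seed(13)
  st <- spike_table(list(a = sort(runif(400, 0, 100)),
                         b = sort(runif(150, 0, 100))),
                    cell_class = "principal")
  nrem <- interval_set(c(5, 40), c(30, 90), label = "NREM")
  off <- interval_set(c(10, 50, 70), c(11, 52, 70.5), label = "OFF")
  mask <- exclusion_mask(nrem, off)
  r <- period_rates(st, mask)
  for (u in names(st$spikes)) {
    inside <- sum(iv_contains(st$spikes[[u]], mask))
    expect_equal(r[[u]], inside / iv_duration(mask))
  }
})

test_that("quintile assignment follows the ceiling rule with stable ties", {
  q <- assign_quintiles(stats::setNames(1:10, sprintf("u%02d", 1:10)))
  expect_equal(unname(q), rep(1:5, each = 2))

  # 7 cells: the ceiling(5 r / 7) rule gives sizes (1, 1, 2, 1, 2)
  q7 <- assign_quintiles(stats::setNames(seq(0.1, 0.7, by = 0.1),
                                         sprintf("u%d", 1:7)))
  expect_equal(unname(q7), c(1, 2, 3, 3, 4, 5, 5))
  expect_equal(as.integer(table(q7)), c(1L, 1L, 2L, 1L, 2L))

  # all-equal rates: tie-break by ascending unit id, sizes differ by <= 1
  qe <- assign_quintiles(stats::setNames(rep(2, 10), sprintf("u%02d", 1:10)))
  expect_equal(unname(qe[order(names(qe))]), rep(1:5, each = 2))
  expect_lte(diff(range(table(qe))), 1)

  expect_error(assign_quintiles(c(a = 1, b = 2)), "at least 5")

  # invariance under strictly monotone transforms of the rates
  set.seed(21)
  r <- stats::setNames(rlnorm(23), sprintf("u%02d", 1:23))
  expect_identical(assign_quintiles(r), assign_quintiles(log(r + 1)))
  expect_identical(assign_quintiles(r), assign_quintiles(r * 100))
})

test_that("quintile traces normalize to exactly 1 over the reference period", {
  set.seed(33)
  n <- 25
  ids <- sprintf("u%02d", 1:n)
  base <- rlnorm(n, 0, 0.5)
  # 12 bins; rates double after bin 6 for every cell
  rates <- outer(base, c(rep(1, 6), rep(2, 6)))
  rm <- structure(list(rates = rates, bin_centers_s = 1:12,
                       occupancy_s = rep(1, 12), unit_ids = ids,
                       cell_class = rep("principal", n)),
                  class = "rate_matrix")
  q <- assign_quintiles(stats::setNames(base, ids))
  tr <- quintile_traces(rm, q, reference_bins = 1:6)
  expect_equal(unname(rowMeans(tr$normalized[, 1:6])), rep(1, 5),
               tolerance = 1e-9)
  expect_equal(unname(tr$normalized[, 7]), rep(2, 5), tolerance = 1e-9)

  # constant population: every normalized trace is identically 1
  rmc <- rm; rmc$rates <- matrix(3, n, 12)
  trc <- quintile_traces(rmc, q, reference_bins = 1:6)
  expect_true(all(abs(trc$normalized - 1) < 1e-12))

  # planted REM-like widening separates normalized traces in order
  fac <- c(0.6, 0.8, 0.9, 1.0, 1.1)
  rmw <- rm
  rmw$rates <- outer(base, rep(1, 12))
  for (j in 7:12) rmw$rates[, j] <- base * fac[q]
  trw <- quintile_traces(rmw, q, reference_bins = 1:6)
  expect_true(all(diff(trw$normalized[, 10]) > 0))
})

test_that("population CV matches hand values and closed forms", {
  expect_equal(population_cv(c(1, 1, 1, 1))$cv, 0)
  expect_equal(population_cv(c(0.5, 1.5))$cv, sqrt(2) / 2, tolerance = 1e-12)
  expect_true(population_cv(c(0, 0, 0))$undefined)
  expect_error(population_cv(1), "at least 2")

  # scale invariance
  set.seed(3)
  r <- rlnorm(50)
  expect_equal(population_cv(r)$cv, population_cv(17 * r)$cv, tolerance = 1e-12)

  # log-normal closed form: CV = sqrt(exp(sigma^2) - 1)
  sigma <- 0.8
  set.seed(4)
  big <- rlnorm(2e5, 0, sigma)
  expect_equal(population_cv(big)$cv, sqrt(exp(sigma^2) - 1), tolerance = 0.02)
})
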