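test_that("change index matches hand values and its invariants", {
  ci <- change_index(c(1, 1, 0.9), c(1, 0, 1.1))
  expect_equal(ci$cells$ci, c(0, 1, -0.1))

  set.seed(41)
  a <- rlnorm(200); b <- rlnorm(200)
  f <- change_index(a, b)$cells$ci
  g <- change_index(b, a)$cells$ci
  expect_equal(f, -g)                                  # antisymmetry
  expect_true(all(f >= -1 & f <= 1))                   # bounded
  expect_equal(change_index(3 * a, 3 * b)$cells$ci, f) # scale invariance

  expect_error(change_index(c(0, 0), c(0, 0)), "silent")
  # both-zero cells are excluded from group accounting but cannot shift the
  # group CI (they add zero to both sums)
  ci2 <- change_index(c(0, 2, 4), c(0, 1, 3), groups = "g")
  expect_equal(ci2$groups$n_excluded, 1L)
  expect_equal(ci2$groups$ci, (2 - 4 / 3) / (2 + 4 / 3))
})

test_that("delta log FR matches hand values and opposes CI in sign", {
  d <- delta_log_fr(c(1, 1, 2), c(1, 10, 0))
  expect_equal(d$dlog[1:2], c(0, 1))
  expect_true(is.na(d$dlog[3]))
  expect_equal(d$n_excluded, 1L)

  set.seed(43)
  a <- rlnorm(300); b <- rlnorm(300)
  dl <- delta_log_fr(a, b)$dlog
  ci <- change_index(a, b)$cells$ci
  nz <- dl != 0
  expect_true(all(sign(dl[nz]) == -sign(ci[nz])))
})

test_that("surrogates are seed-reproducible and handle the degenerate flip", {
  set.seed(45)
  fr_i <- stats::setNames(rlnorm(20), sprintf("u%02d", 1:20))
  fr_k <- stats::setNames(rlnorm(20), names(fr_i))
  s1 <- shuffle_surrogates(fr_i, fr_k, n_shuffles = 50, seed = 99)
  s2 <- shuffle_surrogates(fr_i, fr_k, n_shuffles = 50, seed = 99)
  expect_identical(s1$values, s2$values)

  # identical i and k: every within-state surrogate CI is exactly 0, so the
  # whole across-state change survives as deflection
  s0 <- shuffle_surrogates(fr_i, fr_i, n_shuffles = 20, seed = 1)
  expect_true(all(s0$values == 0))
  q <- assign_quintiles(fr_i)
  ci <- change_index(fr_i, fr_k, paste0("q", q))
  di <- deflection_index(ci, s0)
  expect_equal(di$di, di$observed_ci)
})

test_that("Monte-Carlo surrogates converge to the exhaustive flip oracle", {
  set.seed(47)
  n <- 10
  ids <- sprintf("u%02d", 1:n)
  fr_i <- stats::setNames(rlnorm(n, 0, 0.8), ids)
  fr_k <- stats::setNames(rlnorm(n, 0, 0.8), ids)
  exact <- exhaustive_flip_oracle(fr_i, fr_k, ids)
  mc <- shuffle_surrogates(fr_i, fr_k, n_shuffles = 2000, seed = 7)
  for (g in paste0("q", 1:5)) {
    mc_se <- stats::sd(mc$values[, g]) / sqrt(2000)
    expect_lt(abs(mean(mc$values[, g]) - mean(exact[, g])), 3 * mc_se)
    # MC percentile must land between the exact quantiles at p +/- 3 binomial SEs
    for (p in c(0.025, 0.975)) {
      se_p <- 3 * sqrt(p * (1 - p) / 2000)
      lo <- stats::quantile(exact[, g], max(0, p - se_p), names = FALSE)
      hi <- stats::quantile(exact[, g], min(1, p + se_p), names = FALSE)
      got <- stats::quantile(mc$values[, g], p, names = FALSE)
      expect_gte(got, lo - 1e-12)
      expect_lte(got, hi + 1e-12)
    }
  }
})

test_that("deflection index reports exact differences, ordered bands, valid p", {
  set.seed(49)
  fr_i <- stats::setNames(rlnorm(40), sprintf("u%02d", 1:40))
  fr_j <- stats::setNames(rlnorm(40), names(fr_i))
  fr_k <- stats::setNames(rlnorm(40), names(fr_i))
  q <- assign_quintiles(fr_i)
  ci <- change_index(fr_i, fr_j, paste0("q", q))
  surr <- shuffle_surrogates(fr_i, fr_k, n_shuffles = 400, seed = 3)
  di <- deflection_index(ci, surr)
  expect_equal(di$di, di$observed_ci - di$surrogate_mean)
  expect_true(all(di$band_lo <= di$surrogate_mean &
                    di$surrogate_mean <= di$band_hi))
  expect_true(all(di$p > 0 & di$p <= 1))
})

test_that("interneurons form one fixed surrogate group, never quintiled", {
  set.seed(51)
  n <- 30
  cls <- c(rep("principal", 24), rep("interneuron", 6))
  ids <- sprintf("u%02d", 1:n)
  fr_i <- stats::setNames(rlnorm(n), ids)
  fr_k <- stats::setNames(rlnorm(n), ids)
  s <- shuffle_surrogates(fr_i, fr_k, cell_class = cls, n_shuffles = 30, seed = 2)
  expect_setequal(colnames(s$values), c(paste0("q", 1:5), "interneuron"))
})

test_that("standard-test wrappers behave on degenerate and null inputs", {
  z <- report_tests(rep(0, 12), "signed_rank")
  expect_equal(z$p, 1)
  expect_equal(z$statistic, 0)

  x <- rnorm(50)
  ks <- report_tests(x, "ks", values2 = x)
  expect_equal(ks$statistic, 0)

  # ANOVA type-I error calibration under the null
  set.seed(55)
  hits <- 0L
  reps <- 600
  for (r in seq_len(reps)) {
    v <- rnorm(60)
    g <- rep(1:5, each = 12)
    if (report_tests(v, "anova", groups = g)$p < 0.05) hits <- hits + 1L
  }
  rate <- hits / reps
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})
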