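test_that("degraded_fraction is direct arithmetic on the series", {
  s <- decay_series(c(0, 60), c(17, 17))
  expect_equal(degraded_fraction(s), c(0, 0))
  s2 <- decay_series(c(0, 60), c(17, 8.5))
  expect_equal(degraded_fraction(s2), c(0, 0.5))
  # a series engineered to end at 70.87% degraded
  s3 <- decay_series(c(0, 30, 60), c(40, 20, 40 * (1 - 0.7087)))
  expect_equal(degraded_fraction(s3)[3], 0.7087)
  expect_equal(refractory_fraction(s3), 0.2913)
})

test_that("decay_series validates its invariants", {
  expect_error(decay_series(c(1, 2), c(10, 9)), "first time")
  expect_error(decay_series(c(0, 2, 2), c(10, 9, 8)), "increasing")
  expect_error(decay_series(c(0, 2), c(10, -1)), "nonnegative")
  expect_error(degraded_fraction(decay_series(c(0, 1), c(0, 0))), "positive")
})

test_that("half_life inverts first-order rates", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.1), log(2) / 0.1)
  expect_equal(half_life(log(2) / 198.04), 198.04)
  expect_error(half_life(0), "positive")
})

test_that("predict_degraded has the two-pool limits and monotonicity", {
  fit <- list(fa = 0.5, fb = 0.2, k1 = log(2), k2 = 0.01)
  expect_equal(predict_degraded(fit, 0), 0)
  expect_equal(predict_degraded(fit, 1e6), 0.7, tolerance = 1e-9)
  expect_equal(predict_degraded(list(fa = 0.5, fb = 0, k1 = log(2), k2 = 0.01), 1),
               0.25)
  tt <- seq(0, 100, by = 0.5)
  expect_true(all(diff(predict_degraded(fit, tt)) >= 0))
  expect_true(all(predict_degraded(fit, tt) <= 0.7 + 1e-12))
  expect_error(predict_degraded(fit, -1), "nonnegative")
})

test_that("noiseless two-pool series is recovered to 1e-5 relative error", {
  t <- seq(0, 60, length.out = 13)
  truth <- list(fa = 0.5, fb = 0.3, k1 = 0.5, k2 = 0.01)
  s <- decay_series(t, 40 * (1 - predict_degraded(truth, t)))
  fit <- fit_two_pool(s, seed = 1)
  expect_true(fit$converged)
  rel <- abs(c(fit$fa, fit$fb, fit$k1, fit$k2) /
               unlist(truth) - 1)
  expect_lt(max(rel), 1e-5)
})

test_that("single-pool truth drives the slow pool to zero", {
  t <- seq(0, 60, length.out = 13)
  truth <- list(fa = 0.6, fb = 0, k1 = 0.4, k2 = 0.02)
  s <- decay_series(t, 40 * (1 - predict_degraded(truth, t)))
  fit <- fit_two_pool(s, seed = 2)
  expect_lte(fit$fb, 0.01)
})

test_that("all-zero degraded fractions flag an undefined fit quality", {
  s <- decay_series(seq(0, 60, length.out = 7), rep(40, 7))
  fit <- fit_two_pool(s, seed = 3)
  expect_lt(fit$fa + fit$fb, 0.01)
  expect_true(is.na(fit$r2_adj))
})

test_that("refitting model predictions is a fixed point", {
  t <- c(0, 2, 5, 10, 20, 40, 60)
  s <- decay_series(t, 40 * (1 - predict_degraded(
    list(fa = 0.45, fb = 0.25, k1 = 0.46, k2 = 0.0035), t)))
  f1 <- fit_two_pool(s, seed = 4)
  s2 <- decay_series(t, 40 * (1 - predict_degraded(f1, t)))
  f2 <- fit_two_pool(s2, seed = 5)
  expect_equal(c(f2$fa, f2$fb, f2$k1, f2$k2),
               c(f1$fa, f1$fb, f1$k1, f1$k2), tolerance = 1e-6)
})

test_that("fc + final degraded fraction = 1 exactly", {
  ser <- gen_decay_series(source_profile("DOMg"), seed = 9)[[1]]
  fr <- degraded_fraction(ser)
  expect_identical(refractory_fraction(ser), 1 - fr[length(fr)])
})

test_that("fewer than 5 time points is signalled", {
  s <- decay_series(c(0, 2, 5, 10), c(40, 30, 25, 20))
  expect_error(fit_two_pool(s, seed = 1), "5 time points")
})

test_that("noisy recovery at the 7 sampling days: median fa within 3 pp (scaled-down replicate count)", {
  # the full invariant uses 200 replicates at noise sd 0.5 pp; 60 replicates
  # keep the default test run fast and give the median ample precision
  p <- source_profile("DOMa")
  fa_hat <- vapply(1:60, function(i) {
    ser <- gen_decay_series(p, noise_sd = 0.005, seed = i)[[1]]
    fit_two_pool(ser, seed = i)$fa
  }, 0)
  expect_lt(abs(stats::median(fa_hat) - p$fa), 0.03)
})

test_that("replicate summary returns mean and sd per parameter", {
  sers <- gen_decay_series(source_profile("DOMa"), noise_sd = 0.002, seed = 21)
  res <- fit_two_pool_replicates(sers, seed = 21)
  expect_length(res$fits, 3)
  expect_named(res$mean, c("fa", "fb", "k1", "k2", "fc"))
  expect_true(all(res$sd >= 0))
})
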