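test_that("generators are pure functions of (parameters, seed)", {
  p <- source_profile("DOMa")
  expect_identical(gen_decay_series(p, seed = 1), gen_decay_series(p, seed = 1))
  expect_identical(gen_formula_table(100, seed = 2),
                   gen_formula_table(100, seed = 2))
  expect_identical(gen_peak_list(gen_formula_table(50, seed = 3), seed = 4),
                   gen_peak_list(gen_formula_table(50, seed = 3), seed = 4))
  expect_identical(small_stack(seed = 5)$data, small_stack(seed = 5)$data)
  expect_identical(gen_otu_table(6, 40, seed = 6)$counts,
                   gen_otu_table(6, 40, seed = 6)$counts)
  # different seeds differ
  expect_false(identical(gen_formula_table(100, seed = 2),
                         gen_formula_table(100, seed = 99)))
})

test_that("gen_decay_series reproduces the kinetic curve", {
  p <- source_profile("DOMm")
  sers <- gen_decay_series(p, noise_sd = 0, seed = 1)
  expect_length(sers, 3)
  s <- sers[[1]]
  expect_equal(s$times, c(0, 2, 5, 10, 20, 40, 60))
  expect_equal(degraded_fraction(s), predict_degraded(p, s$times),
               tolerance = 1e-12)
  expect_equal(s$values[1], p$initial_doc)
  # noise averages out (law of large numbers at one day)
  many <- vapply(1:300, function(i) {
    degraded_fraction(gen_decay_series(p, noise_sd = 0.01, seed = i)[[1]])[4]
  }, 0)
  expect_lt(abs(mean(many) - predict_degraded(p, 10)), 3 * 0.01 / sqrt(300))
})

test_that("source presets encode the reported kinetics", {
  a <- source_profile("DOMa")
  expect_equal(a$fa, 0.538)
  expect_equal(log(2) / a$k2, 49.51)
  g <- source_profile("DOMg")
  expect_equal(g$fb, 0.676)
  m <- source_profile("DOMm")
  expect_equal(predict_degraded(m, 1e9), 0.7087, tolerance = 1e-9)
  expect_lte(a$fa + a$fb, 1)
})

test_that("gen_formula_table honours the class mix and window pools", {
  tab <- gen_formula_table(1000, seed = 10)
  prof <- class_profile(tab, "count")
  expect_lt(abs(prof["lignins"] - 80), 4)
  # every emitted formula classifies as a pool class
  mix <- attr(tab, "class_mix")
  expect_true(all(tab$compound_class %in% names(mix)))
  # single-class mix -> all records in that class
  tab2 <- gen_formula_table(50, class_mix = c(carbohydrates = 1), seed = 11)
  expect_true(all(tab2$compound_class == "carbohydrates"))
  expect_error(gen_formula_table(0, seed = 1), "n_formulas")
  expect_error(gen_formula_table(10, class_mix = c(lignins = 0.5), seed = 1),
               "sum to 1")
})

test_that("biodegradation series recovers a planted fate plan", {
  t0 <- gen_formula_table(400, seed = 20)
  plan <- list(consume = c(proteins = 1), produce = c(lignins = 0.3),
               cram_quota = 0.5)
  days <- c(0, 5, 60)
  series <- gen_biodegradation_series(t0, plan, days = days, seed = 21)
  expect_named(series, c("0", "5", "60"))
  # day 0 equals the input
  expect_setequal_chr(series[["0"]]$formula, t0$formula)
  # proteins fully consumed by the final day
  expect_equal(sum(series[["60"]]$compound_class == "proteins"), 0)
  # lignin count grows monotonically
  n_lig <- vapply(series, function(tt) sum(tt$compound_class == "lignins"), 0)
  expect_true(all(diff(n_lig) >= 0))
  expect_gt(n_lig[3], n_lig[1])
  # molecule_fate recovers the plan
  fate <- molecule_fate(series[["0"]], series[["60"]])
  consumed_classes <- unique(fate$compound_class[fate$fate == "consumed"])
  expect_true("proteins" %in% consumed_classes)
  produced <- fate[fate$fate == "produced", ]
  expect_true(all(produced$compound_class == "lignins"))
  expect_gt(mean(produced$is_cram), 0.25) # CRAM quota materialised
  # zero rates: every table identical, every molecule resistant
  still <- gen_biodegradation_series(t0, list(), days = days, seed = 22)
  expect_identical(still[["0"]]$formula, still[["60"]]$formula)
  fate0 <- molecule_fate(still[["0"]], still[["60"]])
  expect_true(all(fate0$fate == "resistant"))
})

test_that("gen_peak_list perturbs masses at ppm scale", {
  tab <- gen_formula_table(100, seed = 30)
  pk <- gen_peak_list(tab, ppm_sd = 0.3, seed = 31)
  mz0 <- neutral_mass(tab) - domlake:::PROTON_MASS
  ppm <- (pk$mz - mz0) / mz0 * 1e6
  expect_lt(abs(stats::sd(ppm) - 0.3), 0.1)
  expect_equal(pk$intensity, tab$intensity)
  # empty table -> empty peak list
  empty <- tab[0, ]
  expect_equal(nrow(gen_peak_list(empty, seed = 1)), 0)
})

test_that("gen_eem_stack composes an exact trilinear tensor at zero noise", {
  st <- small_stack(noise_frac = 0, seed = 40)
  truth <- attr(st, "truth")
  X <- array(0, dim(st$data))
  for (r in seq_len(ncol(truth$scores))) {
    X <- X + truth$scores[, r] %o% truth$em_loadings[, r] %o% truth$ex_loadings[, r]
  }
  expect_equal(st$data, X, tolerance = 1e-12)
  expect_error(gen_eem_stack(4, reference_components(), seed = 1), "at least")
})

test_that("gen_otu_table limits behave", {
  # huge concentration -> near-uniform compositions
  t1 <- gen_otu_table(5, 100, concentration = 1e6, depth = 1e5, seed = 50)
  h <- apply(t1$counts, 2, shannon)
  expect_true(all(abs(h - log(100)) < 0.02))
  # all mass on one OTU -> Shannon 0
  counts <- matrix(0L, 3, 4); counts[1, ] <- 100L
  expect_equal(shannon(otu_table_dl(counts)$counts[, 1]), 0)
})

test_that("planted OTU-feature link is detected with high power", {
  hits <- vapply(1:25, function(i) {
    feat <- seq_len(12)
    otus <- gen_otu_table(12, 40, seed = 100 + i, depth = 5000,
                          planted_feature = feat, planted_otus = 1, effect = 1.5)
    fm <- matrix(feat, 1, 12, dimnames = list("f", colnames(otus$counts)))
    scr <- spearman_screen(fm, otus)
    isTRUE(scr$p["f", "OTU1"] < 0.05)
  }, TRUE)
  expect_gt(mean(hits), 0.9)
})
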