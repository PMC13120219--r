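test_that("tucker_congruence is a normalised dot product", {
  u <- c(1, 2, 3)
  expect_equal(tucker_congruence(u, u), 1)
  expect_equal(tucker_congruence(c(1, 0), c(0, 1)), 0)
  expect_equal(tucker_congruence(u, 3 * u), 1)
  expect_error(tucker_congruence(u, c(0, 0, 0)), "zero-norm")
  expect_error(tucker_congruence(u, c(1, 2)), "length")
})

test_that("noiseless rank-3 stack is recovered with congruence >= 0.999", {
  st <- small_stack(noise_frac = 0, seed = 1)
  m <- parafac_als(st, 3, n_starts = 3, seed = 2)
  expect_lt(m$fit_error, 1e-6)
  truth <- attr(st, "truth")
  em_c <- abs(crossprod(m$em_loadings, truth$em_loadings))
  ex_c <- abs(crossprod(m$ex_loadings, truth$ex_loadings))
  pairs <- domlake:::greedy_match(em_c * ex_c)
  expect_true(all(em_c[pairs] >= 0.999))
  expect_true(all(ex_c[pairs] >= 0.999))
})

test_that("ALS error trace is monotone nonincreasing", {
  st <- small_stack(noise_frac = 0.05, seed = 3)
  m <- parafac_als(st, 3, n_starts = 2, seed = 4)
  expect_true(all(diff(m$error_trace) <= 1e-12))
})

test_that("same seed gives identical models, sample order only permutes scores", {
  st <- small_stack(noise_frac = 0.01, seed = 5)
  m1 <- parafac_als(st, 3, n_starts = 2, seed = 6)
  m2 <- parafac_als(st, 3, n_starts = 2, seed = 6)
  expect_identical(m1$scores, m2$scores)
  expect_identical(m1$em_loadings, m2$em_loadings)
  # permute samples: loadings unchanged up to matching, scores permuted
  perm <- c(5:12, 1:4)
  stp <- structure(list(data = st$data[perm, , ], ex_grid = st$ex_grid,
                        em_grid = st$em_grid,
                        sample_ids = st$sample_ids[perm]),
                   class = "eem_stack")
  m3 <- parafac_als(stp, 3, n_starts = 2, seed = 6)
  cc <- abs(crossprod(m1$em_loadings, m3$em_loadings))
  pairs <- domlake:::greedy_match(cc)
  expect_true(all(cc[pairs] > 0.9999))
  for (i in seq_len(nrow(pairs))) {
    expect_equal(m3$scores[, pairs[i, 2]], m1$scores[perm, pairs[i, 1]],
                 tolerance = 1e-3)
  }
})

test_that("scaling one sample's EEM scales only that sample's scores", {
  st <- small_stack(noise_frac = 0, seed = 7)
  st2 <- st
  st2$data[4, , ] <- 2 * st2$data[4, , ]
  m1 <- parafac_als(st, 3, n_starts = 2, seed = 8)
  m2 <- parafac_als(st2, 3, n_starts = 2, seed = 8)
  cc <- abs(crossprod(m1$em_loadings, m2$em_loadings))
  pairs <- domlake:::greedy_match(cc)
  s1 <- m1$scores[, pairs[, 1], drop = FALSE]
  s2 <- m2$scores[, pairs[, 2], drop = FALSE]
  expect_equal(s2[4, ], 2 * s1[4, ], tolerance = 1e-6)
  expect_equal(s2[-4, ], s1[-4, ], tolerance = 1e-6)
})

test_that("recovered peak positions sit within one grid step at 1% noise", {
  st <- small_stack(noise_frac = 0.01, seed = 9)
  m <- parafac_als(st, 3, n_starts = 2, seed = 10)
  truth <- attr(st, "truth")
  cc <- abs(crossprod(m$em_loadings, truth$em_loadings))
  pairs <- domlake:::greedy_match(cc)
  for (i in seq_len(nrow(pairs))) {
    em_hat <- st$em_grid[which.max(m$em_loadings[, pairs[i, 1]])]
    em_true <- st$em_grid[which.max(truth$em_loadings[, pairs[i, 2]])]
    expect_lte(abs(em_hat - em_true), 5) # one emission grid step
  }
})

test_that("leverage test flags a planted outlier and nothing in a homogeneous stack", {
  st <- small_stack(noise_frac = 0.01, seed = 11)
  m <- parafac_als(st, 3, n_starts = 2, seed = 12)
  expect_length(leverage_outliers(st, m), 0)
  st2 <- st
  st2$data[7, , ] <- 50 * st2$data[7, , ]
  m2 <- parafac_als(st2, 3, n_starts = 2, seed = 12)
  flagged <- leverage_outliers(st2, m2)
  expect_true(7 %in% flagged)
  # flagging does not alter the stack
  expect_identical(dim(st2$data)[1], 12L)
})

test_that("match_components pairs a generator round-trip and honours one-to-one", {
  refs <- reference_components()[1:3]
  st <- small_stack(refs = refs, noise_frac = 0, seed = 13)
  m <- parafac_als(st, 3, n_starts = 2, seed = 14)
  mt <- match_components(m, refs)
  expect_true(all(mt$matched))
  expect_setequal_chr(mt$reference, c("C1", "C2", "C3"))
  # duplicate references: one-to-one leaves the duplicate unmatched
  refs_dup <- list(refs[[1]], refs[[1]], refs[[2]], refs[[3]])
  mt2 <- match_components(m, refs_dup)
  expect_lte(sum(mt2$reference == "C1", na.rm = TRUE), 1)
  # disjoint spectral support: nothing matches
  far <- list(list(name = "Z", ex_peaks = 210, em_peaks = 580))
  mt3 <- match_components(m, far)
  expect_false(any(mt3$matched))
})

test_that("fmax is score x loading maxima and scales with the sample", {
  st <- small_stack(noise_frac = 0, seed = 15)
  m <- parafac_als(st, 3, n_starts = 2, seed = 16)
  fm <- fmax_scores(m)
  expect_equal(dim(fm), c(12L, 3L))
  expect_equal(unname(fm[2, 1]),
               m$scores[2, 1] * max(m$em_loadings[, 1]) * max(m$ex_loadings[, 1]))
  expect_equal(attr(fm, "fdom"), rowSums(fm))
  # zero-score sample gives zero Fmax
  m0 <- m
  m0$scores[3, ] <- 0
  expect_true(all(fmax_scores(m0)[3, ] == 0))
})

test_that("split-half validation recovers the component count on a small stack", {
  st <- small_stack(n_samples = 24, refs = reference_components()[c(1, 4)],
                    noise_frac = 0.01, seed = 17)
  sh <- split_half_validate(st, k_range = 2:3, seed = 18)
  expect_equal(sh$selected_k, 2L)
  expect_error(split_half_validate(small_stack(n_samples = 7,
                                               refs = reference_components()[1:3],
                                               seed = 1), seed = 1),
               "at least 8")
})
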