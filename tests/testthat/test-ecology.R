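test_that("shannon matches closed forms and vegan", {
  expect_equal(shannon(rep(5, 4)), log(4))
  expect_equal(shannon(c(10, 0, 0)), 0)
  expect_equal(shannon(c(2, 1, 1)), -sum(c(.5, .25, .25) * log(c(.5, .25, .25))))
  expect_error(shannon(c(0, 0)), "no counts")
  # zero-count taxa change nothing; uniform maximises for fixed richness
  set.seed(1)
  x <- rpois(20, 30) + 1
  expect_equal(shannon(c(x, 0, 0)), shannon(x))
  expect_lte(shannon(x), log(length(x)))
  skip_if_not_installed("vegan")
  expect_equal(shannon(x), unname(vegan::diversity(x, "shannon")))
})

test_that("bray_curtis matches closed forms and vegan", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(2, 0), c(1, 1)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "empty")
  set.seed(2)
  a <- rpois(30, 10); b <- rpois(30, 10)
  expect_gte(bray_curtis(a, b), 0)
  expect_lte(bray_curtis(a, b), 1)
  expect_equal(bray_curtis(a, b), bray_curtis(b, a))
  skip_if_not_installed("vegan")
  expect_equal(bray_curtis(a, b),
               as.numeric(vegan::vegdist(rbind(a, b), "bray")))
})

test_that("pcoa reproduces Euclidean-realisable distances to 1e-8", {
  set.seed(3)
  pts <- matrix(rnorm(8 * 3), 8, 3)
  D <- as.matrix(dist(pts))
  res <- pcoa_dl(D)
  D2 <- as.matrix(dist(res$points))
  expect_lt(max(abs(D - D2)), 1e-8)
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_lte(sum(res$explained), 1 + 1e-12)
})

test_that("pcoa handles degenerate geometries", {
  # 3 collinear points: 1-D embedding, second axis explains nothing
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  res <- pcoa_dl(D)
  expect_equal(ncol(res$points), 1)
  expect_equal(res$explained[1], 1)
  # identical points: zero coordinates
  res0 <- pcoa_dl(matrix(0, 4, 4))
  expect_equal(ncol(res0$points), 0)
  expect_error(pcoa_dl(matrix(c(0, 1, 2, 0), 2, 2)), "asymmetric")
})

test_that("pcoa agrees with ape's implementation on a Bray-Curtis matrix", {
  skip_if_not_installed("ape")
  otus <- gen_otu_table(10, 50, seed = 4)
  D <- bray_curtis_matrix(otus)
  res <- pcoa_dl(D)
  ref <- ape::pcoa(as.dist(D))
  n_ax <- min(ncol(res$points), ncol(ref$vectors))
  for (j in seq_len(min(3, n_ax))) {
    expect_equal(abs(res$points[, j]), abs(ref$vectors[, j]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("spearman_screen filters, correlates and adjusts", {
  otus <- gen_otu_table(12, 60, seed = 5, concentration = 0.5)
  rel <- sweep(otus$counts, 2, colSums(otus$counts), `/`)
  # feature equal to one OTU's abundance ranking -> rho 1
  target <- which.max(rowMeans(rel))
  feats <- rbind(feat1 = rel[target, ], flat = rep(1, 12))
  colnames(feats) <- colnames(otus$counts)
  scr <- spearman_screen(feats, otus, min_rel_abundance = 0.001)
  expect_equal(scr$rho["feat1", rownames(rel)[target]], 1)
  # constant feature is flagged and excluded
  expect_true("flat" %in% scr$dropped_constant)
  expect_true(all(is.na(scr$rho["flat", ])))
  # abundance filter drops rare OTUs
  kept_ab <- rowMeans(rel)[scr$otus_kept]
  expect_true(all(kept_ab > 0.001))
  # monotone-transform invariance
  feats2 <- rbind(feat1 = exp(3 * rel[target, ]))
  colnames(feats2) <- colnames(otus$counts)
  scr2 <- spearman_screen(feats2, otus)
  expect_equal(scr2$rho["feat1", ], scr$rho["feat1", ])
  # misalignment is signalled
  bad <- feats
  colnames(bad) <- rev(colnames(feats))
  expect_error(spearman_screen(bad, otus), "misaligned")
})

test_that("spearman_screen abundance filter excludes a 0.0005-abundance OTU", {
  counts <- matrix(1000L, 5, 8)
  counts[5, ] <- 2L # rel abundance 2/4002 < 0.001
  otus <- otu_table_dl(counts)
  feats <- matrix(rnorm(8), 1, 8, dimnames = list("f", colnames(otus$counts)))
  scr <- spearman_screen(feats, otus)
  expect_false("OTU5" %in% scr$otus_kept)
  # max-abundance interpretation is available behind a flag
  counts2 <- counts
  counts2[5, 1] <- 100L
  otus2 <- otu_table_dl(counts2)
  scr2 <- spearman_screen(feats, otus2, abundance_stat = "max")
  expect_true("OTU5" %in% scr2$otus_kept)
})
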