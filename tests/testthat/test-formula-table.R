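test_that("formula_table collapses duplicates to the highest intensity", {
  recs <- parse_formula(c("C10H12O6", "C10H12O6", "C5H10O2"))
  recs$intensity <- c(2, 5, 1)
  expect_warning(tab <- formula_table(recs), "duplicate")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$intensity[tab$formula == "C10H12O6"], 5)
  expect_equal(attr(tab, "total_intensity"), 6)
})

test_that("class_profile computes both weightings and sums to 100", {
  tab <- lignin_protein_table()
  pi <- class_profile(tab, "intensity")
  expect_equal(unname(pi["lignins"]), 75)
  expect_equal(unname(pi["proteins"]), 25)
  pc <- class_profile(tab, "count")
  expect_equal(unname(pc["lignins"]), 50)
  expect_equal(sum(pi), 100)
  expect_equal(sum(pc), 100)
  # single-record table -> 100% in its class
  one <- make_table("C10H12O6", 7)
  expect_equal(unname(class_profile(one, "count")["lignins"]), 100)
  expect_equal(unname(class_profile(one, "intensity")["lignins"]), 100)
})

test_that("class_profile sums to 100 for random tables (property)", {
  for (seed in 1:5) {
    tab <- gen_formula_table(200, seed = seed)
    expect_equal(sum(class_profile(tab, "count")), 100)
    expect_equal(sum(class_profile(tab, "intensity")), 100)
  }
})

test_that("jaccard_similarity implements both variants", {
  a <- gen_formula_table(100, seed = 1)
  # construct b sharing exactly 50 formulas with a
  other <- gen_formula_table(300, seed = 2)
  extra <- other[!(other$formula %in% a$formula), ][1:50, ]
  recs <- rbind(as.data.frame(a)[1:50, c("c", "h", "n", "o", "s", "intensity")],
                extra[, c("c", "h", "n", "o", "s", "intensity")])
  b <- formula_table(recs, "b")
  expect_equal(jaccard_similarity(a, b, "as_printed"), 50 / 200)
  expect_equal(jaccard_similarity(a, b, "conventional"), 50 / 150)
  # identical tables: as_printed caps at 0.5, conventional reaches 1
  expect_equal(jaccard_similarity(a, a, "as_printed"), 0.5)
  expect_equal(jaccard_similarity(a, a, "conventional"), 1)
  # disjoint tables -> 0 under both
  d <- formula_table(extra[, c("c", "h", "n", "o", "s", "intensity")], "d")
  expect_equal(jaccard_similarity(a, d, "as_printed"), 0)
  expect_equal(jaccard_similarity(a, d, "conventional"), 0)
  # symmetry
  expect_equal(jaccard_similarity(a, b), jaccard_similarity(b, a))
})

test_that("shared_unique agrees with brute-force set algebra", {
  t1 <- gen_formula_table(120, seed = 10)
  t2 <- gen_formula_table(120, seed = 11)
  t3 <- gen_formula_table(120, seed = 12)
  res <- shared_unique(list(t1, t2, t3))
  k1 <- t1$formula; k2 <- t2$formula; k3 <- t3$formula
  expect_setequal_chr(res$shared, intersect(intersect(k1, k2), k3))
  expect_setequal_chr(res$unique[[1]], setdiff(k1, union(k2, k3)))
  expect_setequal_chr(res$unique[[2]], setdiff(k2, union(k1, k3)))
  expect_setequal_chr(res$unique[[3]], setdiff(k3, union(k1, k2)))
  # identical tables: shared = full set, uniques empty
  res2 <- shared_unique(list(t1, t1))
  expect_setequal_chr(res2$shared, k1)
  expect_length(res2$unique[[1]], 0)
})

test_that("molecule_fate labels presence/absence and fold changes", {
  t0 <- make_table(c("C10H12O6", "C5H10O2", "C6H12O6"), c(5, 5, 5), "t0")
  t1 <- make_table(c("C10H12O6", "C6H12O6", "C15H18O9"), c(20, 5, 5), "t1")
  fate <- molecule_fate(t0, t1)
  lab <- setNames(fate$fate, fate$formula)
  expect_identical(unname(lab["C5H10O2"]), "consumed")   # absent at end
  expect_identical(unname(lab["C15H18O9"]), "produced")  # absent at t0
  expect_identical(unname(lab["C10H12O6"]), "produced")  # rel 1/3 -> 2/3, 2x
  expect_identical(unname(lab["C6H12O6"]), "consumed")   # rel 1/3 -> 1/6
  # equal relative intensities -> resistant
  fate2 <- molecule_fate(t0, t0)
  expect_true(all(fate2$fate == "resistant"))
  # per-class share changes sum to zero (compositional)
  expect_equal(sum(attr(fate, "class_change")), 0)
  expect_equal(sum(attr(fate2, "class_change")), 0)
})
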