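test_that("Shannon index is base-2 entropy of relative abundances", {
  expect_equal(shannonIndex(c(8, 8, 8, 8)), 2.0)
  expect_equal(shannonIndex(c(5, 0, 0)), 0.0)
  expect_equal(shannonIndex(c(3, 1)), 0.8113, tolerance = 1e-4)
  expect_error(shannonIndex(c(0, 0)), "all-zero")
  ft <- randomTable(10, 4, seed = 1)
  h <- shannonIndex(ft)
  expect_named(h, sampleIds(ft))
  expect_equal(unname(h[2]), shannonIndex(featureCounts(ft)[, 2]))
})

test_that("Faith's PD spans present tips and the root", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(unname(faithPD(c(A = 1, B = 1), tr)), 3.0)
  expect_equal(unname(faithPD(c(C = 4), tr)), 2.0)
  expect_equal(unname(faithPD(c(A = 1, B = 1, C = 1), tr)),
               sum(tr$edge.length))
  expect_error(faithPD(c(Z = 1), tr), "not in tree")
})

test_that("Bray-Curtis matches its closed form and bounds", {
  expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(brayCurtis(c(1, 0, 2), c(0, 5, 0)), 1)
  expect_equal(brayCurtis(c(2, 0, 1), c(1, 1, 1)), 1 / 3)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
  ft <- randomTable(12, 5, seed = 4)
  d <- brayCurtisMatrix(ft)
  m <- as.matrix(d)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m["s01", "s03"],
               brayCurtis(featureCounts(ft)[, 1], featureCounts(ft)[, 3]))
})

test_that("UniFrac agrees with direct per-branch summation", {
  # two-tip star, disjoint communities: fully unique branch length
  star <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unifrac(star, c(A = 3), c(B = 5), weighted = FALSE), 1.0)
  # identical communities: zero in both variants
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:1,D:3):2);")
  x <- c(A = 3, B = 1, C = 2, D = 0)
  expect_equal(unifrac(tr, x, x, weighted = FALSE), 0)
  expect_equal(unifrac(tr, x, x, weighted = TRUE), 0)
  # random 8-tip trees vs brute-force branch enumeration
  for (s in 1:5) {
    set.seed(s)
    tr8 <- ape::rphylo(8, 1, 0)
    x <- setNames(rpois(8, 4), tr8$tip.label)
    y <- setNames(rpois(8, 4), tr8$tip.label)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(unifrac(tr8, x, y, weighted = FALSE),
                 unifracBrute(tr8, x, y, weighted = FALSE), tolerance = 1e-10)
    expect_equal(unifrac(tr8, x, y, weighted = TRUE),
                 unifracBrute(tr8, x, y, weighted = TRUE), tolerance = 1e-10)
  }
})

test_that("PCoA is classical scaling with positive axes only", {
  # three mutually equidistant samples: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  p <- pcoaOrdination(d3)
  expect_length(p$eigenvalues, 2)
  expect_equal(p$eigenvalues[1], p$eigenvalues[2], tolerance = 1e-9)

  # collinear points: axis 1 recovers spacing up to sign/translation
  pts <- c(0, 1, 3, 7)
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(paste0("s", 1:4), paste0("s", 1:4))
  p2 <- pcoaOrdination(dm)
  ax1 <- p2$coordinates[, 1]
  expect_equal(as.matrix(dist(ax1)), as.matrix(dist(pts)),
               ignore_attr = TRUE, tolerance = 1e-8)

  # Euclidean-embeddable input: coordinates reconstruct all distances
  set.seed(9)
  X <- matrix(rnorm(6 * 3), 6)
  dm2 <- as.matrix(dist(X))
  dimnames(dm2) <- list(paste0("s", 1:6), paste0("s", 1:6))
  p3 <- pcoaOrdination(dm2)
  expect_equal(as.matrix(dist(p3$coordinates)), dm2,
               ignore_attr = TRUE, tolerance = 1e-8)

  # degenerate all-zero distances: no positive axes
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_length(pcoaOrdination(z)$eigenvalues, 0)
  bad <- d3; bad[1, 2] <- 0.2
  expect_error(pcoaOrdination(bad), "symmetric")
})

test_that("ANOSIM returns its boundary values and matches exhaustive p", {
  ids <- paste0("s", 1:6)
  g <- setNames(rep(c("x", "y"), each = 3), ids)
  # perfect separation: all between > all within
  m <- matrix(0.9, 6, 6, dimnames = list(ids, ids))
  m[1:3, 1:3] <- 0.1; m[4:6, 4:6] <- 0.1
  diag(m) <- 0
  expect_equal(anosimTest(m, g, seed = 1)$R, 1.0)
  # all equal distances: R = 0
  flat <- matrix(0.5, 6, 6, dimnames = list(ids, ids)); diag(flat) <- 0
  expect_equal(anosimTest(flat, g, seed = 1)$R, 0.0)
  # Monte Carlo p within 0.05 of exhaustive enumeration over assignments
  for (s in 1:3) {
    set.seed(s)
    mm <- as.matrix(dist(matrix(rnorm(12), 6)))
    dimnames(mm) <- list(ids, ids)
    res <- anosimTest(mm, g, nPermutations = 999, seed = s)
    expect_lt(abs(res$p_value - anosimExact(mm, unname(g))), 0.05)
  }
  expect_error(anosimTest(flat, setNames(c("x", rep("y", 5)), ids)),
               "at least 2")
})

test_that("Mantel r is the off-diagonal Pearson correlation, p two-sided by permutation", {
  set.seed(2)
  m1 <- as.matrix(dist(matrix(rnorm(10), 5)))
  ids <- paste0("s", 1:5)
  dimnames(m1) <- list(ids, ids)
  expect_equal(mantelTest(m1, m1, nPermutations = 9, seed = 1)$r, 1.0)
  aff <- 0.5 * m1 + 0.1; diag(aff) <- 0
  expect_equal(mantelTest(m1, aff, nPermutations = 9, seed = 1)$r, 1.0)
  # p within 0.05 of exact enumeration over all 120 permutations
  for (s in 1:3) {
    set.seed(100 + s)
    m2 <- as.matrix(dist(matrix(rnorm(10), 5)))
    dimnames(m2) <- list(ids, ids)
    res <- mantelTest(m1, m2, nPermutations = 999, seed = s)
    expect_lt(abs(res$p_value - mantelExact(m1, m2)), 0.05)
  }
  bad <- m1[c(2, 1, 3, 4, 5), c(2, 1, 3, 4, 5)]
  expect_error(mantelTest(m1, bad), "same order")
})

test_that("the Monte Carlo two-sample test matches exhaustive splits and has power", {
  # identical groups: high p by construction
  a <- c(1, 2, 3, 4, 5)
  expect_gt(mcTwoSampleTest(a, a, seed = 1)$p_value, 0.5)
  # extreme 2v2: p equals the smallest achievable, 1/3 over the 6 splits
  res <- mcTwoSampleTest(c(1, 2), c(100, 101), nPermutations = 999, seed = 2)
  expect_lt(abs(res$p_value - welchExact(c(1, 2), c(100, 101))), 0.05)
  expect_equal(welchExact(c(1, 2), c(100, 101)), 1 / 3, tolerance = 1e-12)
  # shift alternative: power above 0.9 at delta = 2 sd
  set.seed(3)
  rej <- replicate(200, {
    mcTwoSampleTest(rnorm(20), rnorm(20, 2), nPermutations = 99)$p_value <= 0.05
  })
  expect_gt(mean(rej), 0.9)
  # both groups constant and equal: null, not an error
  expect_equal(mcTwoSampleTest(c(1, 1), c(1, 1), nPermutations = 99,
                               seed = 1)$p_value, 1.0)
})

test_that("BH adjustment is the step-up procedure, order-preserving", {
  expect_equal(bhAdjust(0.05), 0.05)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(4)
  p <- runif(50)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("dissimilarity partitioning splits pairs by shared group", {
  ids <- paste0("s", 1:4)
  m <- as.matrix(dist(1:4)); dimnames(m) <- list(ids, ids)
  g <- setNames(c("a", "a", "b", "b"), ids)
  parts <- dissimilarityGroups(m, g)
  expect_equal(nrow(parts), 6)
  expect_equal(sum(parts$type == "within"), 2)
  expect_setequal(parts$group[parts$type == "within"], c("a", "b"))
  expect_true(all(is.na(parts$group[parts$type == "between"])))
})
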