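test_that("Spearman rho handles monotone, antitone and tied inputs", {
  expect_equal(spearmanRho(1:6, c(2, 5, 9, 11, 20, 21)), 1.0)
  expect_equal(spearmanRho(1:6, rev(1:6)), -1.0)
  expect_equal(spearmanRho(c(1, 2, 2, 4), c(1, 3, 2, 4)), 0.9487,
               tolerance = 1e-4)
  expect_true(is.na(spearmanRho(c(3, 3, 3, 3), 1:4)))
  expect_error(spearmanRho(1:4, 1:5), "equal length")
})

test_that("networks retain only pairs passing both the rho and the adjusted-p criteria", {
  set.seed(10)
  base <- matrix(rpois(12 * 30, 20), 12, 30,
                 dimnames = list(sprintf("f%02d", 1:12), sprintf("s%02d", 1:30)))
  base[2, ] <- base[1, ]          # identical patterns: forced rho = 1
  net <- suppressMessages(buildNetwork(FeatureTable(base), groupLabel = "g"))
  e <- networkEdges(net)
  expect_true(any(e$feature_a == "f01" & e$feature_b == "f02"))
  expect_equal(e$rho[e$feature_a == "f01" & e$feature_b == "f02"], 1.0)
  # exhaustive audit: every edge satisfies both retention criteria
  expect_true(all(abs(e$rho) > 0.8 & e$p_adjusted <= 0.05))
  expect_true(all(e$sign == ifelse(e$rho > 0, "+", "-")))

  # perfect rho at n = 4 with exact permutation p: min two-sided p is 2/24,
  # so BH cannot reach 0.05 and no edge survives despite |rho| = 1
  m4 <- matrix(rpois(8 * 4, 12), 8, 4,
               dimnames = list(sprintf("f%02d", 1:8), sprintf("s%02d", 1:4)))
  m4[2, ] <- m4[1, ] + 1
  net4 <- suppressMessages(buildNetwork(FeatureTable(m4), groupLabel = "g"))
  expect_equal(nrow(networkEdges(net4)), 0)
})

test_that("exact small-n permutation p-values match direct enumeration", {
  set.seed(11)
  m <- matrix(rpois(5 * 5, 15), 5, 5,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:5)))
  ps <- taxafun:::allPairsSpearman(sweep(m, 2, colSums(m), "/"))
  perms <- permutationsOracle(5)
  for (i in 1:4) for (j in (i + 1):5) {
    x <- rank(m[i, ] / colSums(m))
    y <- rank(m[j, ] / colSums(m))
    rObs <- cor(x, y)
    rPerm <- apply(perms, 1, function(p) cor(x[p], y))
    expect_equal(ps$p[i, j], mean(abs(rPerm) >= abs(rObs) - 1e-12),
                 tolerance = 1e-12)
  }
})

test_that("the edge set is invariant under strictly monotone per-feature transforms", {
  sim <- simulateCounts(simulationConfig(nFeatures = 60, nPlantedEdges = 6,
                                         nPlantedFoldChanges = 0,
                                         depth = 4000), seed = 21)
  ft <- sim$table
  # a strictly monotone per-feature transform of the relative abundances
  # leaves every rank, hence every rho and p, unchanged
  rel <- sweep(featureCounts(ft), 2, colSums(featureCounts(ft)), "/")
  relT <- (rel * 1000)^1.7 + 5
  ps1 <- taxafun:::allPairsSpearman(rel)
  ps2 <- taxafun:::allPairsSpearman(relT)
  expect_equal(ps1$rho, ps2$rho, tolerance = 1e-12)
})

test_that("betweenness matches brute-force shortest-path enumeration", {
  mkNet <- function(edges, label = "g") {
    nodes <- sort(unique(c(edges$feature_a, edges$feature_b)))
    methods::new("CooccurrenceNetwork",
                 edges = cbind(edges, rho = 0.9, sign = "+",
                               p_raw = 0.001, p_adjusted = 0.01),
                 nodes = nodes, groupLabel = label, nPairsTested = 10L)
  }
  star <- mkNet(data.frame(feature_a = "hub",
                           feature_b = c("l1", "l2", "l3")))
  b <- betweennessCentrality(star)
  expect_equal(b[["hub"]], 1.0)
  expect_equal(unname(b[c("l1", "l2", "l3")]), c(0, 0, 0))

  path3 <- mkNet(data.frame(feature_a = c("a", "b"), feature_b = c("b", "c")))
  expect_equal(betweennessCentrality(path3)[["b"]], 1.0)

  # random graphs up to 10 nodes vs the exhaustive path oracle
  for (s in 1:5) {
    set.seed(400 + s)
    n <- sample(6:10, 1)
    nodes <- sprintf("n%02d", 1:n)
    pairs <- t(utils::combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.35
    if (sum(keep) < 2) next
    edges <- data.frame(feature_a = pairs[keep, 1], feature_b = pairs[keep, 2])
    net <- mkNet(edges)
    expect_equal(betweennessCentrality(net),
                 betweennessBrute(edges, networkNodes(net)),
                 tolerance = 1e-10)
  }
})

test_that("topology summarises counts, signs, connectivity and hubs deterministically", {
  edges <- data.frame(
    feature_a = c("a", "b", "c", "d"),
    feature_b = c("b", "c", "d", "a"),
    rho = c(0.9, -0.85, 0.95, 0.9),
    sign = c("+", "-", "+", "+"),
    p_raw = rep(1e-4, 4), p_adjusted = rep(1e-3, 4))
  net <- methods::new("CooccurrenceNetwork", edges = edges,
                      nodes = c("a", "b", "c", "d"), groupLabel = "g",
                      nPairsTested = 6L)
  topo <- networkTopology(net, topK = 2)
  expect_equal(topo$n_nodes, 4)
  expect_equal(topo$n_edges, 4)
  expect_equal(topo$connectivity, 1.0)      # 4-cycle: edges = nodes
  expect_equal(topo$positive_fraction, 0.75)
  expect_equal(topo$negative_fraction, 0.25)
  # 4-cycle betweenness is equal everywhere: hub ties break lexicographically
  expect_identical(topo$hubs, c("a", "b"))

  empty <- methods::new("CooccurrenceNetwork",
                        edges = edges[0, ], nodes = character(0),
                        groupLabel = "g", nPairsTested = 0L)
  t0 <- networkTopology(empty)
  expect_equal(t0$n_nodes, 0)
  expect_equal(t0$connectivity, 0)
  expect_length(t0$hubs, 0)
})

test_that("null data yields few edges and planted structure is recovered", {
  # independent features: BH keeps the network nearly empty
  set.seed(30)
  falseEdges <- replicate(5, {
    m <- matrix(rpois(80 * 15, 30), 80, 15,
                dimnames = list(sprintf("f%02d", 1:80), sprintf("s%02d", 1:15)))
    nrow(networkEdges(suppressMessages(
      buildNetwork(FeatureTable(m), groupLabel = "null"))))
  })
  expect_true(mean(falseEdges) <= 0.05 * choose(80, 2))

  # planted pairs at rho 0.9 are mostly recovered (small-scale check)
  hits <- sapply(1:5, function(s) {
    cfg <- simulationConfig(nFeatures = 100, nPlantedEdges = 15,
                            nPlantedFoldChanges = 0,
                            dispersionMultiplier = c(homozygote = 1,
                                                     heterozygote = 1))
    sim <- simulateCounts(cfg, seed = 500 + s)
    net <- suppressMessages(buildNetwork(sim$table, groupLabel = "all"))
    e <- networkEdges(net)
    got <- paste(e$feature_a, e$feature_b)
    want <- paste(sim$truth$planted_edges$feature_a,
                  sim$truth$planted_edges$feature_b)
    c(sens = mean(want %in% got),
      false = if (nrow(e)) mean(!(got %in% want)) else 0)
  })
  expect_gt(mean(hits["sens", ]), 0.7)
  expect_lt(mean(hits["false", ]), 0.05)
})
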