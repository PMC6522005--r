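smallConfig <- function(...) {
  simulationConfig(nFeatures = 120, nPlantedEdges = 8,
                   nPlantedFoldChanges = 10, nKos = 80, depth = 4000, ...)
}

test_that("simulation is fully deterministic under (config, seed)", {
  cfg <- smallConfig()
  a <- simulateCommunity(cfg, seed = 33)
  b <- simulateCommunity(cfg, seed = 33)
  expect_identical(featureCounts(a$table), featureCounts(b$table))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(koCopies(a$functionMaps$homozygote),
                   koCopies(b$functionMaps$homozygote))
  c2 <- simulateCommunity(cfg, seed = 34)
  expect_false(identical(featureCounts(a$table), featureCounts(c2$table)))
})

test_that("generated tables satisfy the FeatureTable contract and round-trip", {
  sim <- simulateCounts(smallConfig(), seed = 35)
  ft <- sim$table
  expect_true(validObject(ft))
  expect_true(all(sampleSums(ft) == 4000))
  expect_equal(nrow(sim$metadata), 30)
  expect_setequal(sim$metadata$zygosity, c("homozygote", "heterozygote"))
  expect_equal(length(unique(sim$metadata$genotype)), 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureTable(ft, path)
  expect_identical(featureCounts(readFeatureTable(path)), featureCounts(ft))
})

test_that("planted pair correlations concentrate near their targets", {
  hit <- unlist(lapply(1:10, function(s) {
    sim <- simulateCounts(simulationConfig(nFeatures = 150, nPlantedEdges = 5,
                                           nPlantedFoldChanges = 0),
                          seed = 800 + s)
    m <- featureCounts(sim$table)
    e <- sim$truth$planted_edges
    vapply(seq_len(nrow(e)), function(k)
      abs(cor(m[e$feature_a[k], ], m[e$feature_b[k], ],
              method = "spearman")), numeric(1))
  }))
  expect_gte(mean(hit >= 0.7 & hit <= 1), 0.9)
  # signs are respected
  sim <- simulateCounts(simulationConfig(nFeatures = 150, nPlantedEdges = 10,
                                         nPlantedFoldChanges = 0), seed = 900)
  m <- featureCounts(sim$table)
  e <- sim$truth$planted_edges
  emp <- vapply(seq_len(nrow(e)), function(k)
    cor(m[e$feature_a[k], ], m[e$feature_b[k], ], method = "spearman"),
    numeric(1))
  expect_true(all(sign(emp) == sign(e$target_rho)))
})

test_that("without planted structure random pairs are near-uncorrelated", {
  sim <- simulateCounts(simulationConfig(nFeatures = 100, nPlantedEdges = 0,
                                         nPlantedFoldChanges = 0), seed = 36)
  m <- featureCounts(sim$table)
  set.seed(1)
  pairs <- matrix(sample(nrow(m), 200, replace = TRUE), ncol = 2)
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  rho <- abs(apply(pairs, 1, function(ij)
    cor(m[ij[1], ], m[ij[2], ], method = "spearman")))
  expect_lt(mean(rho, na.rm = TRUE), 0.15)
})

test_that("core membership governs prevalence", {
  sim <- simulateCounts(smallConfig(), seed = 37)
  pres <- featureCounts(sim$table) > 0
  core <- sim$truth$core_features
  expect_true(all(rowSums(pres[core, ]) >= 28))  # near-universal presence
  periph <- setdiff(rownames(pres), core)
  expect_lt(mean(rowMeans(pres[periph, ])), 0.9)
})

test_that("simulated trees are binary, complete and usable for references", {
  cfg <- smallConfig()
  tr <- simulateTreeAndReferences(cfg, seed = 38)
  expect_true(ape::is.binary(tr$tree))
  expect_true(ape::is.rooted(tr$tree))
  expect_equal(length(tr$tree$tip.label), cfg$nFeatures)
  expect_true(all(tr$tree$edge.length >= 0))
  expect_true(all(tr$references %in% tr$tree$tip.label))
  expect_equal(length(tr$references), round(0.5 * cfg$nFeatures))

  # reference fraction 1: every community has NSTI exactly 0
  cfg1 <- smallConfig(referenceFraction = 1)
  tr1 <- simulateTreeAndReferences(cfg1, seed = 39)
  sim <- simulateCounts(cfg1, seed = 39)
  ns <- nstiScores(sim$table, tr1$tree, tr1$references)
  expect_true(all(ns$nsti == 0))
  # partial references: positive NSTI for communities with non-references
  cfg3 <- smallConfig(referenceFraction = 0.3)
  tr3 <- simulateTreeAndReferences(cfg3, seed = 40)
  ns3 <- nstiScores(sim$table, tr3$tree, tr3$references)
  expect_true(all(ns3$nsti > 0))
})

test_that("function maps give every KO at least one carrier", {
  taxa <- sprintf("t%03d", 1:50)
  fm <- simulateFunctionMap(taxa, nKos = 40, redundancy = 3, seed = 41)
  expect_true(all(rowSums(koCopies(fm) > 0) >= 1))
  expect_true(all(koCopies(fm) >= 0))
  fm20 <- simulateFunctionMap(taxa, nKos = 40, redundancy = 20, seed = 41)
  expect_gt(mean(rowSums(koCopies(fm20) > 0)),
            mean(rowSums(koCopies(fm) > 0)))
})

test_that("in the redundancy-1 limit taxonomic and functional dissimilarity coincide", {
  sim <- simulateCounts(simulationConfig(nFeatures = 60, nPlantedEdges = 0,
                                         nPlantedFoldChanges = 0,
                                         coreFraction = 1, depth = 8000),
                        seed = 42)
  # bijective map: each KO carried by exactly one distinct taxon
  taxa <- featureIds(sim$table)
  cp <- diag(length(taxa))
  dimnames(cp) <- list(paste0("KO_", taxa), taxa)
  fm <- TaxonFunctionMap(cp)
  tr <- simulateTreeAndReferences(
    simulationConfig(nFeatures = 60, referenceFraction = 1), seed = 42)$tree
  ko <- predictFunctionTable(sim$table, tr, fm)
  r <- mantelTest(brayCurtisMatrix(sim$table), brayCurtisMatrix(ko),
                  nPermutations = 0)$r
  expect_gt(r, 0.999)
})

test_that("phylogenetic guilds partition the tips at the requested granularity", {
  set.seed(43)
  tr <- ape::rphylo(100, 1, 0)
  g <- phyloGuilds(tr, meanSize = 5)
  expect_setequal(unlist(g), tr$tip.label)
  expect_equal(length(unlist(g)), 100)        # a partition: no tip twice
  expect_equal(length(g), 20)
  g1 <- phyloGuilds(tr, meanSize = 1)
  expect_true(all(lengths(g1) == 1))
})
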