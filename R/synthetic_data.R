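#' Simulation configuration for synthetic genotype-structured communities
#'
#' Defaults emulate the shape of a congenic-mouse 16S study: six genotypes
#' (three homozygote, three heterozygote) with five mice each, ~700 OTUs
#' rarefied to 16,000 reads, a core microbiota of ~12% of features, planted
#' feature-pair correlations, planted between-zygosity fold changes, a
#' heterozygote beta-dispersion excess, and a per-zygosity functional
#' redundancy contrast (mean taxa per KO).
#'
#' @param nGenotypes number of genotypes (even; first half homozygote).
#' @param samplesPerGenotype samples (mice) per genotype.
#' @param nFeatures number of taxonomic features (OTUs).
#' @param coreFraction fraction of features present in all samples.
#' @param depth reads per sample (fixed multinomial depth).
#' @param baseLogMean,baseLogSd log-normal base relative-abundance parameters.
#' @param latentSd between-sample s.d. of log abundance within a group.
#' @param dispersionMultiplier named per-zygosity multiplier on
#'   \code{latentSd} (heterozygote default > 1: more dissimilar communities).
#' @param nPlantedEdges number of feature pairs with planted rank correlation.
#' @param plantedRho target |Spearman rho| of planted pairs.
#' @param negativeEdgeFraction fraction of planted edges with negative sign.
#' @param nPlantedFoldChanges number of features with planted fold changes
#'   (half homozygote-enriched, half heterozygote-enriched).
#' @param plantedLog2FC planted |log2 fold change| between zygosity groups.
#' @param redundancy named per-zygosity mean number of taxa carrying each KO.
#' @param nKos number of KO (function) features.
#' @param mapOverlap fraction of KOs whose carrier sets are shared between
#'   the zygosity groups' maps.
#' @param referenceFraction fraction of taxa flagged as sequenced references.
#' @param seed default seed used by the simulators.
#' @return a list of class \code{"simulation_config"}.
#' @export
simulationConfig <- function(nGenotypes = 6,
                             samplesPerGenotype = 5,
                             nFeatures = 700,
                             coreFraction = 0.12,
                             depth = 16000,
                             baseLogMean = 0,
                             baseLogSd = 1.0,
                             latentSd = 0.7,
                             dispersionMultiplier = c(homozygote = 1,
                                                      heterozygote = 1.4),
                             nPlantedEdges = 25,
                             plantedRho = 0.9,
                             negativeEdgeFraction = 0.25,
                             nPlantedFoldChanges = 40,
                             plantedLog2FC = 2,
                             redundancy = c(homozygote = 20,
                                            heterozygote = 2),
                             nKos = 2000,
                             mapOverlap = 0,
                             referenceFraction = 0.5,
                             seed = 1L) {
  if (nGenotypes %% 2 != 0) stop("nGenotypes must be even (half per zygosity)")
  homo <- paste0("H2", c("b", "d", "k", letters[5:26]))[seq_len(nGenotypes / 2)]
  het <- c("H2bd", "H2dk", "H2kb",
           paste0("H2x", seq_len(nGenotypes)))[seq_len(nGenotypes / 2)]
  cfg <- list(
    nGenotypes = nGenotypes, samplesPerGenotype = samplesPerGenotype,
    nFeatures = nFeatures, coreFraction = coreFraction, depth = depth,
    baseLogMean = baseLogMean, baseLogSd = baseLogSd, latentSd = latentSd,
    dispersionMultiplier = dispersionMultiplier,
    nPlantedEdges = nPlantedEdges, plantedRho = plantedRho,
    negativeEdgeFraction = negativeEdgeFraction,
    nPlantedFoldChanges = nPlantedFoldChanges, plantedLog2FC = plantedLog2FC,
    redundancy = redundancy, nKos = nKos, mapOverlap = mapOverlap,
    referenceFraction = referenceFraction, seed = seed,
    genotypes = c(homo, het),
    zygosity = stats::setNames(rep(c("homozygote", "heterozygote"),
                                   each = nGenotypes / 2), c(homo, het))
  )
  structure(cfg, class = "simulation_config")
}

# Spearman target -> latent Gaussian (Pearson) correlation
latentRho <- function(rhoS) 2 * sin(pi * rhoS / 6)

#' Phylogenetically coherent functional guilds
#'
#' Partitions a tree's tips into clades of roughly \code{meanSize} tips by
#' average-linkage clustering of patristic distances. Guilds model groups of
#' related taxa that share functional content (functional content is
#' phylogenetically conserved); they define both the carrier sets of
#' simulated KOs and the units of compensatory abundance dynamics.
#'
#' @param tree rooted \code{phylo}.
#' @param meanSize target mean tips per guild (>= 1).
#' @return list of character vectors partitioning the tip labels.
#' @export
phyloGuilds <- function(tree, meanSize) {
  validateTree(tree)
  n <- length(tree$tip.label)
  k <- max(1L, round(n / meanSize))
  hc <- stats::hclust(stats::as.dist(ape::cophenetic.phylo(tree)),
                      method = "average")
  unname(split(tree$tip.label, stats::cutree(hc, k = k)))
}

# Compensatory ("portfolio") dynamics: within each guild of size m >= 3,
# shrink the abundance-weighted mean fluctuation by c = 1 - 2/m, buffering
# the guild's total abundance (what a KO carried by the guild measures)
# while its members still turn over. The weighting matters: an unweighted
# centering would leave the dominant member's fluctuation, which carries
# most of the guild total, untouched. Guilds of 1-2 taxa have no effective
# substitutes and are left alone.
applyGuildCompensation <- function(Z, guilds, featIds, weights,
                                   exempt = character(0)) {
  for (g in guilds) {
    idx <- match(setdiff(g, exempt), featIds)
    idx <- idx[!is.na(idx)]
    m <- length(idx)
    c0 <- max(0, 1 - 2 / m)
    if (c0 > 0) {
      w <- weights[idx] / sum(weights[idx])
      wmean <- Z[, idx, drop = FALSE] %*% w
      Z[, idx] <- Z[, idx] - c0 * as.vector(wmean)
    }
  }
  Z
}

#' Simulate a genotype-structured OTU table with known ground truth
#'
#' Latent log abundances are drawn per sample from a Gaussian copula whose
#' correlation structure realizes the planted feature pairs; zygosity mean
#' shifts realize the planted fold changes; a per-zygosity variance
#' multiplier realizes the beta-dispersion contrast; peripheral features get
#' per-sample Bernoulli dropout to plant prevalence structure; final counts
#' are multinomial at the fixed depth (rarefied-table semantics). If planted
#' pairs overlap, the implied correlation matrix is repaired by nearest-PSD
#' projection (with a message).
#'
#' When per-zygosity \code{guilds} are supplied (see
#' \code{\link{phyloGuilds}}), each group's within-sample fluctuations are
#' given compensatory dynamics within its own guilds: taxa sharing a guild
#' substitute for one another, buffering the guild total. This is what makes
#' high functional redundancy decouple functional from taxonomic turnover.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed (default \code{config$seed}).
#' @param guilds optional named list (one entry per zygosity group) of
#'   guild partitions, each a list of feature-id vectors.
#' @return list with \code{table} (a \linkS4class{FeatureTable}),
#'   \code{metadata} (sample metadata data.frame) and \code{truth} (planted
#'   edges, fold changes, core membership, group labels).
#' @export
simulateCounts <- function(config, seed = config$seed, guilds = NULL) {
  cfg <- config
  F <- cfg$nFeatures
  gens <- cfg$genotypes
  zyg <- cfg$zygosity
  nPerG <- cfg$samplesPerGenotype
  n <- length(gens) * nPerG
  featIds <- sprintf("OTU%04d", seq_len(F))
  genotype <- rep(gens, each = nPerG)
  sampleId <- paste0(genotype, "_m", rep(seq_len(nPerG), times = length(gens)))
  zygosity <- unname(zyg[genotype])

  withSeed(seed, {
    beta <- stats::rnorm(F, cfg$baseLogMean, cfg$baseLogSd)

    nEdgeFeat <- 2L * cfg$nPlantedEdges
    special <- sample.int(F, nEdgeFeat + cfg$nPlantedFoldChanges)
    edgeFeat <- special[seq_len(nEdgeFeat)]
    fcFeat <- special[nEdgeFeat + seq_len(cfg$nPlantedFoldChanges)]
    # planted features are kept moderately abundant so their signal survives
    # counting noise without letting them dominate community dissimilarity
    beta[special] <- stats::rnorm(length(special), cfg$baseLogMean + 1.2, 0.2)

    edges <- NULL
    if (cfg$nPlantedEdges > 0) {
      a <- edgeFeat[seq_len(cfg$nPlantedEdges)]
      b <- edgeFeat[cfg$nPlantedEdges + seq_len(cfg$nPlantedEdges)]
      neg <- seq_len(cfg$nPlantedEdges) <=
        round(cfg$negativeEdgeFraction * cfg$nPlantedEdges)
      edges <- data.frame(
        feature_a = featIds[pmin(a, b)], feature_b = featIds[pmax(a, b)],
        target_rho = ifelse(neg, -cfg$plantedRho, cfg$plantedRho),
        stringsAsFactors = FALSE)
    }

    lfc <- numeric(F)
    if (cfg$nPlantedFoldChanges > 0)
      lfc[fcFeat] <- rep_len(c(cfg$plantedLog2FC, -cfg$plantedLog2FC),
                             cfg$nPlantedFoldChanges)

    # core membership and planted prevalence for peripheral features
    nCore <- max(round(cfg$coreFraction * F), length(special))
    extra <- setdiff(sample.int(F), special)
    core <- c(special, extra[seq_len(nCore - length(special))])
    prevProb <- stats::runif(F, 0.15, 0.9)
    prevProb[core] <- 1
    # rare taxa are also inconsistently detected: tie abundance to prevalence
    beta <- beta - 1.5 * (1 - prevProb)

    # latent correlated normals; fast exact path for disjoint planted pairs
    Z <- matrix(stats::rnorm(n * F), n, F)
    if (!is.null(edges)) {
      ia <- match(edges$feature_a, featIds)
      ib <- match(edges$feature_b, featIds)
      r <- latentRho(edges$target_rho)
      if (anyDuplicated(c(ia, ib))) {
        message("planted pairs overlap; repairing correlation matrix by nearest-PSD projection")
        Sigma <- diag(F)
        Sigma[cbind(ia, ib)] <- r
        Sigma[cbind(ib, ia)] <- r
        ch <- tryCatch(chol(Sigma), error = function(e) {
          chol(as.matrix(Matrix::nearPD(Sigma, corr = TRUE)$mat))
        })
        Z <- matrix(stats::rnorm(n * F), n, F) %*% ch
      } else {
        Z[, ib] <- sweep(Z[, ia, drop = FALSE], 2, r, "*") +
          sweep(Z[, ib, drop = FALSE], 2, sqrt(1 - r^2), "*")
      }
    }
    # compensatory guild dynamics; planted-edge features are exempt (their
    # dynamics are pinned by the planted interaction, not substitutability)
    if (!is.null(guilds)) {
      for (g in names(guilds)) {
        rows <- which(zygosity == g)
        if (length(rows))
          Z[rows, ] <- applyGuildCompensation(Z[rows, , drop = FALSE],
                                              guilds[[g]], featIds,
                                              weights = exp(beta),
                                              exempt = featIds[edgeFeat])
      }
    }

    tau <- cfg$latentSd * unname(cfg$dispersionMultiplier[zygosity])
    shift <- outer(ifelse(zygosity == "homozygote", 0.5, -0.5) * log(2), lfc)
    logAbund <- matrix(beta, n, F, byrow = TRUE) + shift + tau * Z

    keep <- matrix(stats::rbinom(n * F, 1, rep(prevProb, each = n)), n, F)
    w <- exp(logAbund) * keep
    counts <- vapply(seq_len(n), function(s) {
      p <- w[s, ]
      stats::rmultinom(1, cfg$depth, p / sum(p))[, 1]
    }, numeric(F))
    dimnames(counts) <- list(featIds, sampleId)

    metadata <- data.frame(
      sample_id = sampleId, genotype = genotype, zygosity = zygosity,
      cage = paste0("cage_", genotype), stringsAsFactors = FALSE)
    truth <- list(
      planted_edges = edges,
      planted_log2fc = stats::setNames(lfc[fcFeat], featIds[fcFeat]),
      lfc_numerator = "homozygote",
      core_features = featIds[sort(core)],
      prevalence_prob = stats::setNames(prevProb, featIds),
      group = stats::setNames(zygosity, sampleId),
      genotype = stats::setNames(genotype, sampleId),
      dispersion_multiplier = cfg$dispersionMultiplier,
      seed = seed)
    list(table = FeatureTable(counts), metadata = metadata, truth = truth)
  })
}

#' Simulate a Yule tree over the features and flag sequenced references
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed.
#' @return list with \code{tree} (rooted bifurcating \code{phylo} with
#'   feature-id tips) and \code{references} (sequenced tip ids).
#' @export
simulateTreeAndReferences <- function(config, seed = config$seed) {
  F <- config$nFeatures
  if (F < 2) stop("need at least 2 features")
  withSeed(seed, {
    tree <- ape::rphylo(F, birth = 1, death = 0)
    tree$tip.label <- sprintf("OTU%04d", seq_len(F))
    nRef <- max(1L, round(config$referenceFraction * F))
    references <- sort(sample(tree$tip.label, nRef))
    list(tree = tree, references = references)
  })
}

#' Simulate a taxon-to-KO map with tunable redundancy
#'
#' Each KO is carried (one copy) by a Poisson(\code{redundancy})-sized set of
#' taxa, never fewer than one. As redundancy approaches 1 the map approaches
#' a bijection and taxonomic/functional dissimilarities coincide; high
#' redundancy decouples them.
#'
#' @param taxa character vector of (reference) taxon ids.
#' @param nKos number of KOs.
#' @param redundancy mean carriers per KO (>= 1).
#' @param seed optional integer seed.
#' @param carriers optional pre-drawn carrier sets (list of taxon-id vectors)
#'   for a leading subset of KOs, used to share content between group maps.
#' @return a \linkS4class{TaxonFunctionMap}.
#' @export
simulateFunctionMap <- function(taxa, nKos = 200, redundancy = 2,
                                seed = NULL, carriers = NULL) {
  if (redundancy < 1) stop("redundancy must be >= 1")
  withSeed(seed, {
    koIds <- sprintf("K%05d", seq_len(nKos))
    m <- matrix(0, nKos, length(taxa), dimnames = list(koIds, taxa))
    for (k in seq_len(nKos)) {
      if (!is.null(carriers) && k <= length(carriers)) {
        set <- carriers[[k]]
      } else {
        size <- min(max(1L, stats::rpois(1, redundancy)), length(taxa))
        set <- sample(taxa, size)
      }
      m[k, set] <- 1
    }
    TaxonFunctionMap(m, references = taxa)
  })
}

#' Per-zygosity function maps with a shared-content fraction
#'
#' Builds one \linkS4class{TaxonFunctionMap} per zygosity group at that
#' group's redundancy (from \code{config$redundancy}). A leading
#' \code{config$mapOverlap} fraction of KOs shares identical carrier sets
#' across groups. Without \code{guilds}, carrier sets are independent
#' Poisson-sized random taxon sets (shared sets drawn at the mean
#' redundancy). With per-group \code{guilds} (\code{\link{phyloGuilds}}),
#' each KO's carriers are the reference members of one randomly chosen guild
#' of its group's partition, and shared KOs draw their guild from the
#' coarsest partition.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param taxa reference taxon ids.
#' @param seed integer seed.
#' @param guilds optional named per-group list of guild partitions over all
#'   features.
#' @return named list of \linkS4class{TaxonFunctionMap}, one per group.
#' @export
simulateGroupFunctionMaps <- function(config, taxa, seed = config$seed,
                                      guilds = NULL) {
  withSeed(seed, {
    nShared <- round(config$mapOverlap * config$nKos)
    if (is.null(guilds)) {
      sharedSets <- NULL
      if (nShared > 0) {
        meanRed <- mean(config$redundancy)
        sharedSets <- lapply(seq_len(nShared), function(k) {
          size <- min(max(1L, stats::rpois(1, meanRed)), length(taxa))
          sample(taxa, size)
        })
      }
      return(lapply(config$redundancy, function(red)
        simulateFunctionMap(taxa, nKos = config$nKos, redundancy = red,
                            carriers = sharedSets)))
    }
    # guild-based carriers: reference members of one guild per KO
    refSets <- lapply(guilds, function(part) {
      gr <- lapply(part, function(g) intersect(g, taxa))
      gr[lengths(gr) > 0]
    })
    coarse <- names(which.max(vapply(guilds, function(p) mean(lengths(p)),
                                     numeric(1))))
    sharedSets <- if (nShared > 0)
      refSets[[coarse]][sample.int(length(refSets[[coarse]]), nShared,
                                   replace = TRUE)]
    lapply(stats::setNames(names(config$redundancy),
                           names(config$redundancy)), function(g) {
      pool <- refSets[[g]]
      own <- pool[sample.int(length(pool), config$nKos - nShared,
                             replace = TRUE)]
      simulateFunctionMap(taxa, nKos = config$nKos,
                          redundancy = config$redundancy[[g]],
                          carriers = c(sharedSets, own))
    })
  })
}

#' Simulate a complete study: counts, metadata, tree, references, maps
#'
#' Convenience wrapper producing every input the analysis pipeline needs,
#' plus the ground-truth record. Fully deterministic under
#' \code{(config, seed)}.
#'
#' The per-zygosity redundancy contrast is realized through phylogenetic
#' guilds (\code{\link{phyloGuilds}}): each group's KO carrier sets are
#' clades of mean size equal to that group's redundancy, and the group's
#' abundance dynamics compensate within those same clades, so high
#' redundancy buffers functional turnover against taxonomic turnover.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed (default \code{config$seed}).
#' @return list with \code{table}, \code{metadata}, \code{truth},
#'   \code{tree}, \code{references}, \code{functionMaps} and \code{guilds}.
#' @export
simulateCommunity <- function(config = simulationConfig(),
                              seed = config$seed) {
  tr <- simulateTreeAndReferences(config, seed = seed + 1L)
  guilds <- lapply(config$redundancy, function(red)
    phyloGuilds(tr$tree, red))
  maps <- simulateGroupFunctionMaps(config, tr$references, seed = seed + 2L,
                                    guilds = guilds)
  cc <- simulateCounts(config, seed = seed, guilds = guilds)
  c(cc, tr, list(functionMaps = maps, guilds = guilds))
}
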