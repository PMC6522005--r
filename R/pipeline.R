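#' Pipeline run configuration
#'
#' @param depth rarefaction depth (reads per sample).
#' @param prevalenceThreshold core-microbiota prevalence threshold.
#' @param rhoThreshold,alpha network edge retention thresholds.
#' @param anosimPermutations,mantelPermutations,mcPermutations,aucPermutations
#'   permutation counts for the respective tests.
#' @param topK hubs reported per network.
#' @param networkLevel fit networks per \code{"genotype"}, per
#'   \code{"zygosity"}, or \code{"both"}.
#' @param minTotal minimum feature total for differential abundance.
#' @param seed integer seed governing every stochastic stage.
#' @return list of class \code{"run_config"}.
#' @export
runConfig <- function(depth = 16000, prevalenceThreshold = 1.0,
                      rhoThreshold = 0.8, alpha = 0.05,
                      anosimPermutations = 99, mantelPermutations = 999,
                      mcPermutations = 999, aucPermutations = 999,
                      topK = 7, networkLevel = c("both", "genotype",
                                                 "zygosity"),
                      minTotal = 1, seed = 1L) {
  networkLevel <- match.arg(networkLevel)
  stopifnot(depth >= 1, prevalenceThreshold > 0, prevalenceThreshold <= 1,
            rhoThreshold >= 0, rhoThreshold < 1, alpha > 0, alpha <= 1)
  structure(as.list(environment()), class = "run_config")
}

zygosityGroups <- function(md) stats::setNames(md$zygosity, md$sample_id)

#' Run the end-to-end form-and-function analysis
#'
#' Sequences the full analysis: ingest and validation, singleton removal,
#' rarefaction, overall/core split, alpha and beta diversity with group
#' tests and ordination, per-group co-occurrence networks with topology,
#' taxonomy-function coupling (Mantel) and prevalence decay/AUC contrasts,
#' and differential abundance between zygosity groups. Deterministic given
#' (inputs, config seed).
#'
#' @param table a \linkS4class{FeatureTable} or path to one (TSV).
#' @param metadata sample metadata data.frame or TSV path (columns
#'   sample_id, genotype, zygosity, cage).
#' @param tree optional \code{phylo} or newick path (enables PD and NSTI).
#' @param functionMaps optional \linkS4class{TaxonFunctionMap}, or a named
#'   list of one map per zygosity group (enables the function arm).
#' @param config a \code{\link{runConfig}}.
#' @return list of class \code{"analysis_report"}: per-stage results, the
#'   config, seeds, and a structured filtering log.
#' @export
runPipeline <- function(table, metadata, tree = NULL, functionMaps = NULL,
                        config = runConfig()) {
  if (is.character(table)) table <- readFeatureTable(table)
  if (is.character(metadata)) metadata <- readSampleMetadata(metadata)
  if (is.character(tree)) tree <- readTree(tree)
  validateSampleMetadata(metadata)
  assertFeatureTable(table)
  log <- list()
  seed <- config$seed

  md <- matchMetadata(table, metadata)

  nBefore <- length(featureIds(table))
  table <- removeSingletons(table)
  log$singletons_removed <- nBefore - length(featureIds(table))

  nSamples <- length(sampleIds(table))
  table <- suppressMessages(rarefy(table, depth = config$depth, seed = seed))
  log$samples_dropped_below_depth <- nSamples - length(sampleIds(table))
  md <- matchMetadata(table, metadata)
  zyg <- zygosityGroups(md)
  homoSamples <- md$sample_id[md$zygosity == "homozygote"]
  hetSamples <- md$sample_id[md$zygosity == "heterozygote"]

  coreIds <- coreFeatures(table, config$prevalenceThreshold)
  coreTable <- table[coreIds, ]
  log$n_features_overall <- length(featureIds(table))
  log$n_features_core <- length(coreIds)

  ## alpha diversity
  shannon <- shannonIndex(table)
  alpha <- list(shannon = shannon,
                shannon_test = mcTwoSampleTest(
                  shannon[homoSamples], shannon[hetSamples],
                  nPermutations = config$mcPermutations, seed = seed + 11L))
  if (!is.null(tree) && all(featureIds(table) %in% tree$tip.label)) {
    pd <- faithPD(table, tree)
    alpha$faith_pd <- pd
    alpha$pd_test <- mcTwoSampleTest(pd[homoSamples], pd[hetSamples],
                                     nPermutations = config$mcPermutations,
                                     seed = seed + 12L)
  }

  ## beta diversity: overall and core
  beta <- list()
  for (scope in c("overall", "core")) {
    tb <- if (scope == "overall") table else coreTable
    if (!length(featureIds(tb))) next
    d <- brayCurtisMatrix(tb)
    parts <- dissimilarityGroups(d, zyg)
    wh <- parts$value[parts$type == "within" & parts$group == "homozygote"]
    wt <- parts$value[parts$type == "within" & parts$group == "heterozygote"]
    beta[[scope]] <- list(
      distance = d,
      pcoa = pcoaOrdination(d),
      anosim = anosimTest(d, zyg, nPermutations = config$anosimPermutations,
                          seed = seed + 21L),
      dissimilarity = parts,
      within_group_test = mcTwoSampleTest(
        wh, wt, nPermutations = config$mcPermutations, seed = seed + 22L))
  }

  ## co-occurrence networks
  networks <- list()
  lvls <- switch(config$networkLevel,
                 both = c("genotype", "zygosity"),
                 config$networkLevel)
  for (lvl in lvls) {
    groups <- if (lvl == "genotype") md$genotype else md$zygosity
    for (g in unique(groups)) {
      ids <- md$sample_id[groups == g]
      if (length(ids) < 4) next
      net <- suppressMessages(buildNetwork(
        table, groupSamples = ids, rhoThreshold = config$rhoThreshold,
        alpha = config$alpha, groupLabel = g))
      networks[[g]] <- list(network = net,
                            topology = networkTopology(net, config$topK))
    }
  }

  ## functional arm
  functional <- NULL
  if (!is.null(functionMaps) && !is.null(tree)) {
    maps <- if (methods::is(functionMaps, "TaxonFunctionMap"))
      list(homozygote = functionMaps, heterozygote = functionMaps)
    else functionMaps
    koParts <- lapply(c(homozygote = "homozygote",
                        heterozygote = "heterozygote"), function(g) {
      ids <- md$sample_id[md$zygosity == g]
      suppressMessages(
        predictFunctionTable(table[, ids], tree, maps[[g]]))
    })
    if (!identical(featureIds(koParts[[1]]), featureIds(koParts[[2]])))
      stop("group function maps must share one KO universe")
    koTable <- FeatureTable(
      cbind(featureCounts(koParts$homozygote),
            featureCounts(koParts$heterozygote))[, md$sample_id],
      featureKind = "function")
    mantel <- lapply(c(homozygote = "homozygote",
                       heterozygote = "heterozygote"), function(g) {
      ids <- md$sample_id[md$zygosity == g]
      mantelTest(brayCurtisMatrix(table[, ids]),
                 brayCurtisMatrix(koTable[, ids]),
                 nPermutations = config$mantelPermutations, seed = seed + 31L)
    })
    richness <- functionalRichness(koTable)
    functional <- list(
      ko_table = koTable,
      mantel = mantel,
      richness = richness,
      richness_test = mcTwoSampleTest(
        richness[homoSamples], richness[hetSamples],
        nPermutations = config$mcPermutations, seed = seed + 32L),
      nsti = nstiScores(table, tree, referenceTaxa(maps[[1]])))
  }

  ## decay curves and AUC contrasts
  decay <- list(
    taxa = lapply(c(homozygote = "homozygote",
                    heterozygote = "heterozygote"), function(g)
      decayCurve(table[, md$sample_id[md$zygosity == g]])),
    taxa_auc = compareAuc(table, zyg,
                          nPermutations = config$aucPermutations,
                          seed = seed + 41L))
  if (!is.null(functional)) {
    decay$functional <- lapply(c(homozygote = "homozygote",
                                 heterozygote = "heterozygote"), function(g)
      decayCurve(functional$ko_table[, md$sample_id[md$zygosity == g]]))
    decay$functional_auc <- compareAuc(functional$ko_table, zyg,
                                       nPermutations = config$aucPermutations,
                                       seed = seed + 42L)
  }

  ## differential abundance (positive log2FC = homozygote-enriched)
  da <- list(taxa = suppressMessages(
    nbWaldTest(table, zyg, minTotal = config$minTotal,
               numerator = "homozygote")))
  if (!is.null(functional))
    da$functional <- suppressMessages(
      nbWaldTest(functional$ko_table, zyg, minTotal = config$minTotal,
                 numerator = "homozygote"))

  structure(list(
    config = config, seed = seed, log = log, metadata = md,
    table = table, core_features = coreIds,
    alpha = alpha, beta = beta, networks = networks,
    functional = functional, decay = decay, differential = da
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report\n")
  cat(sprintf("  %d samples, %d features (%d core)\n",
              nrow(x$metadata), x$log$n_features_overall,
              x$log$n_features_core))
  if (!is.null(x$beta$overall))
    cat(sprintf("  overall ANOSIM: R = %.3f, P = %.3g\n",
                x$beta$overall$anosim$R, x$beta$overall$anosim$p_value))
  if (!is.null(x$functional))
    cat(sprintf("  Mantel r (taxa~function): homozygote %.3f, heterozygote %.3f\n",
                x$functional$mantel$homozygote$r,
                x$functional$mantel$heterozygote$r))
  nsig <- sum(x$differential$taxa$p_adjusted < 0.05)
  cat(sprintf("  differentially abundant taxa (BH P < 0.05): %d\n", nsig))
  invisible(x)
}

#' Write an analysis report to a directory of TSV/JSON files
#'
#' Every statistic in the report is written alongside the stage tables it was
#' computed from: alpha diversity, square Bray-Curtis matrices, PCoA
#' coordinates, network edge lists and topology, decay curves, differential
#' abundance tables, NSTI scores and a JSON summary embedding config and seed.
#'
#' @param report an \code{"analysis_report"}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name, rn = FALSE)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)

  alpha <- data.frame(sample_id = names(report$alpha$shannon),
                      shannon = unname(report$alpha$shannon))
  if (!is.null(report$alpha$faith_pd))
    alpha$faith_pd <- unname(report$alpha$faith_pd[alpha$sample_id])
  tsv(alpha, "alpha_diversity.tsv")

  for (scope in names(report$beta)) {
    m <- as.matrix(report$beta[[scope]]$distance)
    utils::write.table(cbind(sample_id = rownames(m), m),
                       file.path(dir, paste0("bray_curtis_", scope, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tsv(as.data.frame(report$beta[[scope]]$pcoa$coordinates),
        paste0("pcoa_", scope, ".tsv"), rn = TRUE)
  }

  for (g in names(report$networks)) {
    writeEdgeList(report$networks[[g]]$network,
                  file.path(dir, paste0("network_", g, ".tsv")))
  }
  topo <- do.call(rbind, lapply(report$networks, function(x) {
    t <- x$topology
    data.frame(group = t$group, n_nodes = t$n_nodes, n_edges = t$n_edges,
               connectivity = t$connectivity,
               positive_fraction = t$positive_fraction,
               hubs = paste(t$hubs, collapse = ","))
  }))
  if (!is.null(topo)) tsv(topo, "network_topology.tsv")

  for (kind in intersect(c("taxa", "functional"), names(report$decay))) {
    curves <- report$decay[[kind]]
    df <- do.call(rbind, lapply(names(curves), function(g)
      cbind(group = g, curves[[g]])))
    tsv(df, paste0("decay_", kind, ".tsv"))
  }

  tsv(report$differential$taxa, "differential_taxa.tsv")
  if (!is.null(report$differential$functional))
    tsv(report$differential$functional, "differential_functional.tsv")
  if (!is.null(report$functional))
    tsv(report$functional$nsti, "nsti.tsv")

  summary <- list(
    config = report$config[setdiff(names(report$config), "networkLevel")],
    network_level = report$config$networkLevel,
    seed = report$seed,
    log = report$log,
    anosim = lapply(report$beta, function(b)
      list(R = b$anosim$R, p = b$anosim$p_value)),
    alpha_tests = list(shannon_p = report$alpha$shannon_test$p_value),
    within_group_dissimilarity_p = lapply(report$beta, function(b)
      b$within_group_test$p_value),
    mantel = if (!is.null(report$functional))
      lapply(report$functional$mantel, function(m)
        list(r = m$r, p = m$p_value)),
    auc = list(taxa = unclass(report$decay$taxa_auc)[
      c("groups", "auc_a", "auc_b", "p_value")],
      functional = if (!is.null(report$decay$functional_auc))
        unclass(report$decay$functional_auc)[
          c("groups", "auc_a", "auc_b", "p_value")]),
    n_differential_taxa = sum(report$differential$taxa$p_adjusted < 0.05)
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
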