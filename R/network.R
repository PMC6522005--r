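#' Spearman rank correlation
#'
#' Pearson correlation of average-rank transforms (ties get average ranks).
#' Returns \code{NA} when either vector is constant (rho undefined).
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @return rho in [-1, 1], or \code{NA}.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

# all permutations of 1..n as an (n! x n) matrix
allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, pos] <- n
    out[rows, -pos] <- sub
  }
  out
}

# rho matrix and p matrix for all feature pairs of a (features x samples)
# matrix of within-group abundances. Exact permutation p (full enumeration)
# for n <= maxExact samples, else two-sided t approximation on n-2 df.
allPairsSpearman <- function(m, maxExact = 8L) {
  n <- ncol(m)
  ranks <- t(apply(m, 1, rank))
  ranks <- ranks - rowMeans(ranks)
  nrm <- sqrt(rowSums(ranks^2))
  rn <- ranks / nrm
  rho <- tcrossprod(rn)
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  if (n <= maxExact) {
    perms <- allPermutations(n)
    np <- nrow(perms)
    absObs <- abs(rho) - 1e-12
    count <- matrix(0, nrow(m), nrow(m))
    for (b in seq_len(np)) {
      rp <- tcrossprod(rn[, perms[b, ], drop = FALSE], rn)
      count <- count + (abs(rp) >= absObs)
    }
    p <- count / np
  } else {
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p[abs(rho) >= 1 - 1e-12] <- 0
  }
  list(rho = rho, p = p, n = n)
}

#' Build a co-occurrence network for one sample group
#'
#' Computes Spearman correlations between all feature pairs on within-group
#' relative abundances, BH-adjusts the two-sided p-values across all tested
#' pairs, and retains pairs with |rho| above \code{rhoThreshold} AND adjusted
#' p at or below \code{alpha}. With \code{maxExact} or fewer samples the
#' p-values come from full enumeration of sample permutations (the t
#' approximation is invalid at such n); otherwise from the t approximation on
#' n - 2 df. Constant features are skipped with a message.
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param groupSamples sample ids to use (default: all samples).
#' @param rhoThreshold minimum |rho| (default 0.8, exclusive).
#' @param alpha maximum BH-adjusted p (default 0.05, inclusive).
#' @param groupLabel label recorded on the network.
#' @param maxExact largest group size for exact permutation p (default 8).
#' @return a \linkS4class{CooccurrenceNetwork}.
#' @export
buildNetwork <- function(x, groupSamples = NULL, rhoThreshold = 0.8,
                         alpha = 0.05, groupLabel = "all",
                         maxExact = 8L) {
  assertFeatureTable(x)
  if (!is.null(groupSamples)) {
    miss <- setdiff(groupSamples, sampleIds(x))
    if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
    x <- x[, groupSamples]
  }
  m <- featureCounts(x)
  if (ncol(m) < 4) stop("need at least 4 samples in the group")
  if (nrow(m) < 2) stop("need at least 2 features")
  rel <- sweep(m, 2, colSums(m), "/")
  constant <- apply(rel, 1, function(v) stats::sd(v) == 0)
  if (any(constant))
    message("skipping ", sum(constant), " constant feature(s)")
  rel <- rel[!constant, , drop = FALSE]
  ids <- rownames(rel)
  if (length(ids) < 2) {
    edges <- data.frame(feature_a = character(0), feature_b = character(0),
                        rho = numeric(0), sign = character(0),
                        p_raw = numeric(0), p_adjusted = numeric(0))
    return(new("CooccurrenceNetwork", edges = edges, nodes = character(0),
               groupLabel = groupLabel, nPairsTested = 0L))
  }
  ps <- allPairsSpearman(rel, maxExact = maxExact)
  ut <- which(upper.tri(ps$rho), arr.ind = TRUE)
  rho <- ps$rho[ut]
  praw <- ps$p[ut]
  padj <- stats::p.adjust(praw, method = "BH")
  keep <- abs(rho) > rhoThreshold & padj <= alpha
  edges <- data.frame(
    feature_a = ids[ut[keep, 1]],
    feature_b = ids[ut[keep, 2]],
    rho = rho[keep],
    sign = ifelse(rho[keep] > 0, "+", "-"),
    p_raw = praw[keep],
    p_adjusted = padj[keep],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$feature_a, edges$feature_b), , drop = FALSE]
  rownames(edges) <- NULL
  new("CooccurrenceNetwork", edges = edges,
      nodes = sort(unique(c(edges$feature_a, edges$feature_b))),
      groupLabel = groupLabel, nPairsTested = nrow(ut))
}

asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    networkEdges(net)[, c("feature_a", "feature_b")],
    directed = FALSE,
    vertices = data.frame(name = networkNodes(net)))
}

#' Normalized betweenness centrality
#'
#' Unweighted shortest-path betweenness with even splitting among equally
#' short paths, normalized by (n-1)(n-2)/2 where n is the network's node
#' count; disconnected pairs contribute nothing.
#'
#' @param net a \linkS4class{CooccurrenceNetwork}.
#' @return named numeric vector, one value in [0, 1] per node.
#' @export
betweennessCentrality <- function(net) {
  nodes <- networkNodes(net)
  if (length(nodes) < 3)
    return(stats::setNames(rep(0, length(nodes)), nodes))
  g <- asIgraph(net)
  b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  b[nodes]
}

#' Topology summary of a co-occurrence network
#'
#' Node/edge counts, connectivity (edges/nodes), edge sign fractions,
#' normalized betweenness per node and the top-k hub features by betweenness
#' (ties broken by feature id).
#'
#' @param net a \linkS4class{CooccurrenceNetwork}.
#' @param topK number of hubs to report (default 7).
#' @return list of class \code{"network_topology"}.
#' @export
networkTopology <- function(net, topK = 7) {
  e <- networkEdges(net)
  nodes <- networkNodes(net)
  nNodes <- length(nodes)
  nEdges <- nrow(e)
  btw <- betweennessCentrality(net)
  ord <- order(-btw, names(btw))
  hubs <- names(btw)[ord][seq_len(min(topK, nNodes))]
  structure(list(
    group = groupLabel(net),
    n_nodes = nNodes,
    n_edges = nEdges,
    connectivity = if (nNodes) nEdges / nNodes else 0,
    positive_fraction = if (nEdges) mean(e$sign == "+") else 0,
    negative_fraction = if (nEdges) mean(e$sign == "-") else 0,
    betweenness = btw,
    hubs = hubs
  ), class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf(
    "Network topology [%s]: %d nodes, %d edges, connectivity %.2f (%.0f%% positive)\n",
    x$group, x$n_nodes, x$n_edges, x$connectivity, 100 * x$positive_fraction))
  if (length(x$hubs))
    cat("  hubs:", paste(x$hubs, collapse = ", "), "\n")
  invisible(x)
}

#' Write a network's edge list as TSV
#'
#' @param net a \linkS4class{CooccurrenceNetwork}.
#' @param path output path.
#' @export
writeEdgeList <- function(net, path) {
  utils::write.table(networkEdges(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
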