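# Independent brute-force oracles and small fixture builders. These must not
# share code paths with the implementations they check.

randomTable <- function(nFeatures, nSamples, lambda = 10, seed = NULL,
                        featureKind = "taxon") {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(nFeatures * nSamples, lambda), nFeatures, nSamples,
              dimnames = list(sprintf("f%03d", seq_len(nFeatures)),
                              sprintf("s%02d", seq_len(nSamples))))
  FeatureTable(m, featureKind = featureKind)
}

# expected shared features over random k-subsets, by exhaustive enumeration
decayBrute <- function(ft) {
  pres <- featureCounts(ft) > 0
  N <- ncol(pres)
  vapply(seq_len(N), function(k) {
    subs <- utils::combn(N, k)
    mean(apply(subs, 2, function(cols)
      sum(rowSums(pres[, cols, drop = FALSE]) == k)))
  }, numeric(1))
}

# normalized betweenness by explicit shortest-path counting (BFS per source)
betweennessBrute <- function(edges, nodes) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    adj[edges$feature_a[i], edges$feature_b[i]] <- TRUE
    adj[edges$feature_b[i], edges$feature_a[i]] <- TRUE
  }
  score <- setNames(numeric(n), nodes)
  # count shortest paths s->t through v by enumerating all shortest paths
  allPaths <- function(s, t, dist_s) {
    if (s == t) return(list(s))
    out <- list()
    for (u in nodes[adj[, t] & dist_s[nodes] == dist_s[t] - 1]) {
      for (p in allPaths(s, u, dist_s)) out[[length(out) + 1]] <- c(p, t)
    }
    out
  }
  bfs <- function(s) {
    d <- setNames(rep(Inf, n), nodes)
    d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- character(0)
      for (u in frontier) {
        nb <- nodes[adj[u, ]]
        newly <- nb[d[nb] == Inf]
        d[newly] <- d[u] + 1
        nxt <- c(nxt, newly)
      }
      frontier <- unique(nxt)
    }
    d
  }
  for (si in seq_len(n - 1)) for (ti in (si + 1):n) {
    s <- nodes[si]; t <- nodes[ti]
    d <- bfs(s)
    if (!is.finite(d[t])) next
    paths <- allPaths(s, t, d)
    through <- table(unlist(lapply(paths, function(p) setdiff(p, c(s, t)))))
    if (length(through))
      score[names(through)] <- score[names(through)] +
        as.numeric(through) / length(paths)
  }
  score / ((n - 1) * (n - 2) / 2)
}

# UniFrac by direct per-branch summation over tip descendants
unifracBrute <- function(tree, x, y, weighted = FALSE) {
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  xs <- x / sum(x); ys <- y / sum(y)
  num <- den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- desc[[tree$edge[e, 2]]]
    l <- tree$edge.length[e]
    if (weighted) {
      num <- num + l * abs(sum(xs[tips], na.rm = TRUE) -
                           sum(ys[tips], na.rm = TRUE))
    } else {
      inx <- sum(x[tips], na.rm = TRUE) > 0
      iny <- sum(y[tips], na.rm = TRUE) > 0
      if (inx || iny) den <- den + l
      if (xor(inx, iny)) num <- num + l
    }
  }
  if (weighted) num else num / den
}

# exact two-sided Mantel p over all n! simultaneous row/column permutations
mantelExact <- function(m1, m2) {
  n <- nrow(m1)
  lt <- lower.tri(m1)
  r_obs <- cor(m1[lt], m2[lt])
  perms <- permutationsOracle(n)
  rs <- apply(perms, 1, function(p) cor(m1[lt], m2[p, p][lt]))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# exact two-sided Welch-permutation p over all distinct splits
welchExact <- function(a, b) {
  welch <- function(u, v) {
    va <- var(u) / length(u); vb <- var(v) / length(v)
    d <- mean(u) - mean(v)
    if (va + vb == 0) return(if (d == 0) 0 else sign(d) * Inf)
    d / sqrt(va + vb)
  }
  pooled <- c(a, b)
  splits <- utils::combn(length(pooled), length(a))
  t_obs <- welch(a, b)
  ts <- apply(splits, 2, function(ix) welch(pooled[ix], pooled[-ix]))
  mean(abs(ts) >= abs(t_obs) - 1e-12)
}

# exact ANOSIM p over all distinct balanced assignments
anosimExact <- function(m, groups) {
  n <- nrow(m)
  anosimR <- function(g) {
    rks <- rank(m[lower.tri(m)])
    pair <- which(lower.tri(m), arr.ind = TRUE)
    within <- g[pair[, 1]] == g[pair[, 2]]
    (mean(rks[!within]) - mean(rks[within])) / (n * (n - 1) / 4)
  }
  r_obs <- anosimR(groups)
  lv <- unique(groups)
  na <- sum(groups == lv[1])
  assigns <- utils::combn(n, na)
  rs <- apply(assigns, 2, function(ix) {
    g <- rep(lv[2], n); g[ix] <- lv[1]; anosimR(g)
  })
  mean(rs >= r_obs - 1e-12)
}

permutationsOracle <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutationsOracle(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    if (pos == 1) cbind(n, sub)
    else if (pos == n) cbind(sub, n)
    else cbind(sub[, 1:(pos - 1), drop = FALSE], n,
               sub[, pos:(n - 1), drop = FALSE])
  }))
}

# patristic distances via an independent weighted-graph shortest path
patristicOracle <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  d <- igraph::distances(g, weights = tree$edge.length)
  tipIdx <- as.character(seq_along(tree$tip.label))
  out <- d[tipIdx, tipIdx]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}
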