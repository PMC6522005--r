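#' Shannon diversity (bits)
#'
#' Shannon entropy of a sample's relative abundances in log base 2, the
#' QIIME-1 convention: H = -sum p_i log2 p_i over features with p_i > 0.
#'
#' @param x a non-negative count vector (one sample) or a
#'   \linkS4class{FeatureTable} (one value per sample).
#' @return numeric value, or a named vector per sample for a table.
#' @examples
#' shannonIndex(c(8, 8, 8, 8))  # 2 bits
#' @export
shannonIndex <- function(x) {
  if (methods::is(x, "FeatureTable")) {
    m <- featureCounts(x)
    return(vapply(seq_len(ncol(m)),
                  function(j) shannonIndex(m[, j]), numeric(1)) |>
             stats::setNames(colnames(m)))
  }
  if (any(x < 0)) stop("counts must be non-negative")
  if (sum(x) == 0) stop("all-zero sample has no Shannon diversity")
  as.numeric(vegan::diversity(x, index = "shannon", base = 2))
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal rooted subtree spanning a sample's
#' present features (computed with \pkg{picante}, including the root).
#'
#' @param x a \linkS4class{FeatureTable} or a named presence/count vector.
#' @param tree rooted \code{phylo} whose tips cover all present features.
#' @return named numeric vector of PD per sample.
#' @export
faithPD <- function(x, tree) {
  validateTree(tree)
  if (methods::is(x, "FeatureTable")) {
    m <- featureCounts(x)
  } else {
    if (is.null(names(x))) stop("presence vector must be named by feature id")
    m <- matrix(x, ncol = 1, dimnames = list(names(x), "sample"))
  }
  present <- rownames(m)[rowSums(m) > 0]
  unknown <- setdiff(present, tree$tip.label)
  if (length(unknown))
    stop("feature(s) not in tree: ", paste(unknown, collapse = ", "))
  res <- picante::pd(t(m), tree, include.root = TRUE)
  stats::setNames(res$PD, rownames(res))
}

#' Bray-Curtis dissimilarity between two samples
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i), in [0, 1].
#'
#' @param x,y equal-length non-negative abundance vectors, not both all-zero.
#' @return dissimilarity in [0, 1].
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  if (sum(x) == 0 && sum(y) == 0)
    stop("Bray-Curtis undefined for two all-zero samples")
  sum(abs(x - y)) / sum(x + y)
}

#' Bray-Curtis distance matrix over a table's samples
#'
#' @param x a \linkS4class{FeatureTable}.
#' @return a \code{dist} with sample labels.
#' @export
brayCurtisMatrix <- function(x) {
  assertFeatureTable(x)
  if (any(sampleSums(x) == 0)) stop("all-zero sample(s) present")
  vegan::vegdist(t(featureCounts(x)), method = "bray")
}

#' UniFrac distance between two communities
#'
#' Unweighted UniFrac is the branch length unique to either sample's tip set
#' over the branch length covered by their union. Weighted UniFrac is the raw
#' (non-normalized) variant, sum_b l_b |A_b - B_b| over proportional
#' abundances descending each branch; set \code{normalized = TRUE} for the
#' normalized variant. Computed with \pkg{phyloseq}.
#'
#' @param tree rooted \code{phylo}.
#' @param x,y named non-negative abundance vectors (names are tree tips).
#' @param weighted use abundance-weighted UniFrac.
#' @param normalized normalize the weighted variant to [0, 1].
#' @return the UniFrac distance.
#' @export
unifrac <- function(tree, x, y, weighted = FALSE, normalized = FALSE) {
  if (is.null(names(x)) || is.null(names(y)))
    stop("abundance vectors must be named by tree tip")
  if (sum(x) == 0 || sum(y) == 0) stop("empty community")
  ids <- union(names(x), names(y))
  m <- matrix(0, length(ids), 2, dimnames = list(ids, c("x", "y")))
  m[names(x), "x"] <- x
  m[names(y), "y"] <- y
  ft <- FeatureTable(round(m))
  as.numeric(unifracMatrix(ft, tree, weighted = weighted,
                           normalized = normalized))
}

#' @rdname unifrac
#' @param ft a \linkS4class{FeatureTable} of taxa.
#' @return \code{unifracMatrix}: a \code{dist} over the table's samples.
#' @export
unifracMatrix <- function(ft, tree, weighted = FALSE, normalized = FALSE) {
  assertFeatureTable(ft)
  validateTree(tree)
  unknown <- setdiff(featureIds(ft), tree$tip.label)
  if (length(unknown))
    stop("feature(s) not in tree: ", paste(unknown, collapse = ", "))
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(featureCounts(ft), taxa_are_rows = TRUE),
    phyloseq::phy_tree(tree))
  phyloseq::UniFrac(ps, weighted = weighted, normalized = normalized)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers -D^2/2 and eigendecomposes it; axes with non-positive
#' eigenvalues are discarded without correction.
#'
#' @param d a \code{dist} or symmetric zero-diagonal matrix.
#' @return list with \code{coordinates} (samples x axes), \code{eigenvalues}
#'   (positive, descending) and \code{proportionExplained} (relative to the
#'   positive eigenvalue total).
#' @export
pcoaOrdination <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix must have zero diagonal")
  n <- nrow(m)
  if (n < 3) stop("PCoA needs at least 3 samples")
  # negative eigenvalues are expected for non-Euclidean dissimilarities;
  # cmdscale warns about them, we discard those axes below
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- 1e-8 * max(abs(eig), 1e-12)
  pos <- which(eig > tol)
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  if (length(pos)) colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(
    coordinates = coords,
    eigenvalues = eig[pos],
    proportionExplained = if (length(pos)) eig[pos] / sum(eig[pos]) else numeric(0)
  ), class = "taxafun_pcoa")
}

#' @export
print.taxafun_pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes; PCo1 explains %.1f%%\n",
              nrow(x$coordinates), length(x$eigenvalues),
              100 * x$proportionExplained[1]))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities, via \pkg{vegan}. R = (mean between-group
#' rank - mean within-group rank) / (M/2) with M = n(n-1)/2.
#'
#' @param d a \code{dist} or symmetric matrix of sample dissimilarities.
#' @param groups group labels, named by sample id or in sample order.
#' @param nPermutations number of label permutations (default 99).
#' @param seed optional integer seed.
#' @return list with \code{R}, \code{p_value}, \code{n_permutations}.
#' @export
anosimTest <- function(d, groups, nPermutations = 99, seed = NULL) {
  m <- as.matrix(d)
  groups <- alignGroups(groups, rownames(m))
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("every group needs at least 2 samples")
  fit <- withSeed(seed, suppressMessages(
    vegan::anosim(stats::as.dist(m), grouping = factor(groups),
                  permutations = nPermutations)))
  structure(list(R = unname(fit$statistic), p_value = unname(fit$signif),
                 n_permutations = fit$permutations),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, P = %.4g (%d permutations)\n",
              x$R, x$p_value, x$n_permutations))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of corresponding off-diagonal entries, with a
#' two-sided permutation p-value obtained by simultaneous row/column
#' shuffling of the second matrix (add-one estimator).
#'
#' @param d1,d2 \code{dist} objects or symmetric matrices over the same
#'   samples in the same order.
#' @param nPermutations permutations (default 999).
#' @param seed optional integer seed.
#' @return list with \code{r}, \code{p_value}, \code{n_permutations}.
#' @export
mantelTest <- function(d1, d2, nPermutations = 999, seed = NULL) {
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  if (!identical(dim(m1), dim(m2)))
    stop("distance matrices must have the same dimensions")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("sample ids must match and be in the same order")
  n <- nrow(m1)
  lt <- which(lower.tri(m1), arr.ind = TRUE)
  v1 <- m1[lt]
  r_obs <- stats::cor(v1, m2[lt])
  exceed <- 0L
  withSeed(seed, {
    for (b in seq_len(nPermutations)) {
      idx <- sample.int(n)
      v2p <- m2[cbind(idx[lt[, 1]], idx[lt[, 2]])]
      if (abs(stats::cor(v1, v2p)) >= abs(r_obs) - 1e-12) exceed <- exceed + 1L
    }
  })
  structure(list(r = r_obs,
                 p_value = (1 + exceed) / (1 + nPermutations),
                 n_permutations = nPermutations),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.3f, P = %.4g (%d permutations)\n",
              x$r, x$p_value, x$n_permutations))
  invisible(x)
}

# Welch t statistic; 0 when both groups are constant with equal means,
# +/-Inf when constant with different means.
welchT <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  num <- mean(a) - mean(b)
  if (va + vb == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / sqrt(va + vb)
}

#' Nonparametric two-sample test with Monte Carlo permutations
#'
#' Welch t statistic with a two-sided permutation p-value from random label
#' reassignments, p = (1 + #{|t_perm| >= |t_obs|}) / (1 + nPermutations).
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param nPermutations permutations (default 999).
#' @param seed optional integer seed.
#' @return list with \code{t}, \code{p_value}, \code{n_permutations}.
#' @export
mcTwoSampleTest <- function(a, b, nPermutations = 999, seed = NULL) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  t_obs <- welchT(a, b)
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  exceed <- 0L
  withSeed(seed, {
    for (bb in seq_len(nPermutations)) {
      ia <- sample.int(n, na)
      tp <- welchT(pooled[ia], pooled[-ia])
      if (is.nan(tp)) tp <- 0
      if (abs(tp) >= abs(t_obs) - 1e-12) exceed <- exceed + 1L
    }
  })
  structure(list(t = t_obs,
                 p_value = (1 + exceed) / (1 + nPermutations),
                 n_permutations = nPermutations),
            class = "mc_test_result")
}

#' @export
print.mc_test_result <- function(x, ...) {
  cat(sprintf("MC two-sample test: t = %.3f, P = %.4g (%d permutations)\n",
              x$t, x$p_value, x$n_permutations))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1; input
#' order is preserved. Rejects p-values outside [0, 1].
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Partition pairwise dissimilarities by group membership
#'
#' Splits the off-diagonal entries of a distance matrix into within-group and
#' between-group sets, the construction behind within/between dissimilarity
#' boxplots.
#'
#' @param d a \code{dist} or symmetric matrix.
#' @param groups group labels, named by sample id or in sample order.
#' @return data.frame with columns sample_a, sample_b, value, type
#'   ("within"/"between"), group (the shared group for within pairs, NA
#'   otherwise).
#' @export
dissimilarityGroups <- function(d, groups) {
  m <- as.matrix(d)
  groups <- alignGroups(groups, rownames(m))
  lt <- which(lower.tri(m), arr.ind = TRUE)
  ga <- groups[lt[, 1]]
  gb <- groups[lt[, 2]]
  within <- ga == gb
  data.frame(
    sample_a = rownames(m)[lt[, 1]],
    sample_b = rownames(m)[lt[, 2]],
    value = m[lt],
    type = ifelse(within, "within", "between"),
    group = ifelse(within, ga, NA_character_),
    stringsAsFactors = FALSE
  )
}
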