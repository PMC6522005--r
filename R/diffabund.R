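#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: each sample's median ratio of its counts
#' to the per-feature geometric means, computed over features with positive
#' counts in every sample, then rescaled so the factors have geometric mean 1.
#' When no feature is positive everywhere, geometric means fall back to
#' positive counts only (with a message).
#'
#' @param x a \linkS4class{FeatureTable} or count matrix (features x samples).
#' @return named positive numeric vector, one factor per sample.
#' @export
sizeFactorsMedianRatios <- function(x) {
  m <- if (methods::is(x, "FeatureTable")) featureCounts(x) else as.matrix(x)
  if (!nrow(m) || !ncol(m)) stop("empty table")
  logm <- log(m)
  allPos <- rowSums(m > 0) == ncol(m)
  if (any(allPos)) {
    logGeo <- rowMeans(logm)
    s <- apply(m, 2, function(col) {
      r <- log(col) - logGeo
      exp(stats::median(r[allPos]))
    })
  } else {
    message("no feature positive in every sample; using positive-part geometric means")
    logGeo <- apply(logm, 1, function(v) mean(v[is.finite(v)]))
    use <- rowSums(m > 0) > 0
    s <- apply(m, 2, function(col) {
      r <- log(col) - logGeo
      exp(stats::median(r[use & col > 0 & is.finite(logGeo)]))
    })
  }
  if (any(!is.finite(s) | s <= 0))
    stop("could not compute a positive size factor for every sample")
  s <- s / exp(mean(log(s)))
  stats::setNames(s, colnames(m))
}

#' Negative-binomial Wald test for differential abundance
#'
#' Simplified DESeq2-style procedure: counts are normalized by
#' median-of-ratios size factors; per-feature dispersion is estimated by
#' method-of-moments on the normalized counts within groups (floored at
#' 1e-8); the log2 fold change contrasts group mean normalized counts (with a
#' 0.5 pseudo-mean when a group mean is zero); the Wald statistic
#' z = log2FC / SE is referred to the standard normal, two-sided, and BH
#' adjustment is applied across all tested features. No dispersion or LFC
#' shrinkage, no independent filtering.
#'
#' The sign convention follows the numerator group: positive log2 fold
#' changes mean enrichment in \code{numerator} (by default the
#' \code{"homozygote"} level when present, else the first label), negative
#' values enrichment in the other group.
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param groups two-level labels, named by sample id or in sample order;
#'   each group needs >= 3 samples.
#' @param minTotal features with total raw count below this are skipped
#'   (default 1: only all-zero features are skipped).
#' @param numerator group whose enrichment gets positive log2FC.
#' @return data.frame with columns feature_id, base_mean, log2_fold_change,
#'   standard_error, p_value, p_adjusted, ordered as in the input table.
#'   Excluded features and the reason are attached as
#'   \code{attr(res, "excluded")}.
#' @export
nbWaldTest <- function(x, groups, minTotal = 1, numerator = NULL) {
  assertFeatureTable(x)
  m <- featureCounts(x)
  groups <- alignGroups(groups, colnames(m))
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  if (is.null(numerator))
    numerator <- if ("homozygote" %in% lv) "homozygote" else lv[1]
  if (!numerator %in% lv) stop("numerator must be one of the group labels")
  denominator <- setdiff(lv, numerator)
  isNum <- groups == numerator
  if (sum(isNum) < 3 || sum(!isNum) < 3)
    stop("each group needs at least 3 samples")

  tested <- rowSums(m) >= minTotal
  excluded <- data.frame(
    feature_id = rownames(m)[!tested],
    reason = rep(sprintf("total count below %g", minTotal), sum(!tested)),
    stringsAsFactors = FALSE)

  s <- sizeFactorsMedianRatios(m)
  q <- sweep(m, 2, s, "/")
  qn <- q[tested, isNum, drop = FALSE]
  qd <- q[tested, !isNum, drop = FALSE]
  n1 <- ncol(qn)
  n2 <- ncol(qd)
  mu1 <- rowMeans(qn)
  mu2 <- rowMeans(qd)
  v1 <- apply(qn, 1, stats::var)
  v2 <- apply(qd, 1, stats::var)

  # method-of-moments dispersion, pooled over groups with positive means
  dispOne <- function(mu, v) ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  a1 <- dispOne(mu1, v1)
  a2 <- dispOne(mu2, v2)
  w1 <- ifelse(is.na(a1), 0, n1 - 1)
  w2 <- ifelse(is.na(a2), 0, n2 - 1)
  alpha <- (ifelse(is.na(a1), 0, a1) * w1 + ifelse(is.na(a2), 0, a2) * w2) /
    pmax(w1 + w2, 1)
  alpha <- pmax(alpha, 1e-8)

  # 0.5 pseudo-mean whenever a group mean is zero, applied to both groups
  pseudo <- (mu1 == 0 | mu2 == 0) * 0.5
  m1 <- mu1 + pseudo
  m2 <- mu2 + pseudo
  lfc <- log2(m1 / m2)
  varLog <- function(mu, n) (mu + alpha * mu^2) / (n * mu^2)
  se <- sqrt(varLog(m1, n1) + varLog(m2, n2)) / log(2)
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  res <- data.frame(
    feature_id = rownames(m)[tested],
    base_mean = rowMeans(q[tested, , drop = FALSE]),
    log2_fold_change = lfc,
    standard_error = se,
    p_value = p,
    p_adjusted = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  attr(res, "contrast") <- c(numerator = numerator, denominator = denominator)
  res
}

#' Write differential-abundance results as TSV
#'
#' Mirrors the supplementary-table layout: feature id, optional taxonomy
#' passthrough, log2 fold change, p, adjusted p.
#'
#' @param res result of \code{\link{nbWaldTest}}.
#' @param path output path.
#' @param taxonomy optional named lineage vector for annotation passthrough.
#' @export
writeDifferentialResults <- function(res, path, taxonomy = NULL) {
  out <- res
  if (!is.null(taxonomy))
    out$taxonomy <- unname(taxonomy[out$feature_id])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
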