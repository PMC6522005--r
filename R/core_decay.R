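#' Core features at a prevalence threshold
#'
#' Features whose presence (count > 0) frequency across samples is at least
#' \code{prevalenceThreshold}. The default 1.0 gives the core microbiota:
#' features present in 100% of samples.
#'
#' @param x a \linkS4class{FeatureTable} with at least one sample.
#' @param prevalenceThreshold required presence fraction, in (0, 1].
#' @return character vector of core feature ids.
#' @export
coreFeatures <- function(x, prevalenceThreshold = 1.0) {
  assertFeatureTable(x)
  if (!ncol(featureCounts(x))) stop("empty table")
  if (prevalenceThreshold <= 0 || prevalenceThreshold > 1)
    stop("prevalenceThreshold must be in (0, 1]")
  prev <- rowMeans(featureCounts(x) > 0)
  featureIds(x)[prev >= prevalenceThreshold - 1e-12]
}

# per-prevalence expected-shared contributions: row p+1 = prevalence p,
# column k; entry = C(p, k) / C(N, k)
decayWeights <- function(N) {
  k <- seq_len(N)
  p <- 0:N
  w <- exp(outer(p, k, lchoose) - matrix(lchoose(N, k), N + 1, N, byrow = TRUE))
  w[outer(p, k, `<`)] <- 0
  w
}

#' Prevalence decay curve
#'
#' Expected number of features present in every member of a random k-subset
#' of samples, for k = 1..N. The default computes the exact expectation in
#' closed form: E[shared(k)] = sum_f C(prev_f, k) / C(N, k). The
#' \code{"accumulation"} method instead intersects samples cumulatively along
#' a fixed ordering (a sensitivity-analysis variant; ordering-dependent).
#'
#' @param x a \linkS4class{FeatureTable} with >= 2 samples.
#' @param method \code{"expectation"} (default, order-free) or
#'   \code{"accumulation"}.
#' @param order sample ordering for the accumulation method (default: table
#'   order).
#' @return data.frame with columns \code{k} and \code{expected_shared},
#'   class \code{"decay_curve"}.
#' @export
decayCurve <- function(x, method = c("expectation", "accumulation"),
                       order = NULL) {
  assertFeatureTable(x)
  method <- match.arg(method)
  m <- featureCounts(x) > 0
  N <- ncol(m)
  if (N < 2) stop("decay curve needs at least 2 samples")
  if (method == "expectation") {
    prev <- rowSums(m)
    cnt <- tabulate(prev + 1L, nbins = N + 1L)
    y <- as.numeric(cnt %*% decayWeights(N))
  } else {
    if (is.null(order)) order <- seq_len(N)
    shared <- rep(TRUE, nrow(m))
    y <- numeric(N)
    for (k in seq_len(N)) {
      shared <- shared & m[, order[k]]
      y[k] <- sum(shared)
    }
  }
  structure(data.frame(k = seq_len(N), expected_shared = y),
            class = c("decay_curve", "data.frame"))
}

#' Area under a decay curve
#'
#' Trapezoidal rule over the curve's k grid (unit spacing for k = 1..N).
#'
#' @param curve a decay curve data.frame with columns k and expected_shared,
#'   >= 2 points.
#' @return the trapezoidal area.
#' @export
decayAuc <- function(curve) {
  k <- curve$k
  y <- curve$expected_shared
  if (length(k) < 2) stop("AUC needs at least 2 points")
  sum(diff(k) * (y[-1] + y[-length(y)]) / 2)
}

# per-prevalence AUC contribution lookup (prevalence 0..N -> trapezoid area)
aucContrib <- function(N) {
  w <- decayWeights(N)
  tw <- c(0.5, rep(1, N - 2), 0.5)
  as.numeric(w %*% tw)
}

#' Compare decay-curve AUCs between two sample groups
#'
#' Observed statistic is |AUC_a - AUC_b| from the two groups' exact decay
#' curves; significance by permuting group labels (group sizes preserved)
#' with the add-one estimator.
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param groups two-level labels, named by sample id or in sample order.
#' @param nPermutations permutations (default 999).
#' @param seed optional integer seed.
#' @return list with per-group AUCs, observed difference, \code{p_value} and
#'   \code{n_permutations}.
#' @export
compareAuc <- function(x, groups, nPermutations = 999, seed = NULL) {
  assertFeatureTable(x)
  pres <- featureCounts(x) > 0
  groups <- alignGroups(groups, colnames(pres))
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  na <- sum(groups == lv[1])
  nb <- sum(groups == lv[2])
  if (na < 2 || nb < 2) stop("each group needs at least 2 samples")
  contribA <- aucContrib(na)
  contribB <- if (nb == na) contribA else aucContrib(nb)
  groupAuc <- function(isA) {
    prevA <- rowSums(pres[, isA, drop = FALSE])
    prevB <- rowSums(pres[, !isA, drop = FALSE])
    c(sum(contribA[prevA + 1L]), sum(contribB[prevB + 1L]))
  }
  obs <- groupAuc(groups == lv[1])
  d_obs <- abs(obs[1] - obs[2])
  n <- length(groups)
  exceed <- 0L
  withSeed(seed, {
    for (b in seq_len(nPermutations)) {
      isA <- logical(n)
      isA[sample.int(n, na)] <- TRUE
      perm <- groupAuc(isA)
      if (abs(perm[1] - perm[2]) >= d_obs - 1e-9) exceed <- exceed + 1L
    }
  })
  structure(list(
    groups = lv,
    auc_a = obs[1], auc_b = obs[2],
    observed_difference = d_obs,
    p_value = (1 + exceed) / (1 + nPermutations),
    n_permutations = nPermutations
  ), class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("AUC comparison: %s = %.2f vs %s = %.2f, |diff| = %.2f, P = %.4g\n",
              x$groups[1], x$auc_a, x$groups[2], x$auc_b,
              x$observed_difference, x$p_value))
  invisible(x)
}
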