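# patristic distance matrix restricted to query tips x reference tips,
# with lexicographic tie-breaking helper for nearest-reference lookup
nearestReferenceLookup <- function(tree, tips, references) {
  validateTree(tree)
  if (!length(references)) stop("reference set is empty")
  unknown <- setdiff(c(tips, references), tree$tip.label)
  if (length(unknown))
    stop("tip(s) not in tree: ", paste(unknown, collapse = ", "))
  D <- ape::cophenetic.phylo(tree)
  refs <- sort(references)                 # lexicographic tie-break
  Dq <- D[tips, refs, drop = FALSE]
  self <- match(tips, refs)
  hit <- max.col(-Dq, ties.method = "first")
  # a reference tip is its own nearest reference at distance 0
  hit[!is.na(self)] <- self[!is.na(self)]
  data.frame(
    tip = tips,
    reference = refs[hit],
    distance = Dq[cbind(seq_along(tips), hit)],
    stringsAsFactors = FALSE
  )
}

#' Nearest sequenced (reference) taxon
#'
#' The reference tip minimizing patristic (branch-length path) distance to
#' \code{tip}; ties are broken lexicographically by reference id.
#'
#' @param tree rooted \code{phylo}.
#' @param tip query tip label.
#' @param references character vector of reference tip labels (non-empty).
#' @return list with \code{reference} and \code{distance}.
#' @export
nearestSequencedTaxon <- function(tree, tip, references) {
  lk <- nearestReferenceLookup(tree, tip, references)
  list(reference = lk$reference[1], distance = lk$distance[1])
}

#' Weighted Nearest Sequenced Taxon Index (NSTI)
#'
#' Per sample, the abundance-weighted mean patristic distance from each
#' observed taxon to its nearest sequenced reference:
#' NSTI = sum_i a_i d_i / sum_i a_i. A score of 0 means every observed taxon
#' is itself a reference; lower scores mean function prediction is better
#' grounded in sequenced genomes.
#'
#' @param x a \linkS4class{FeatureTable} of taxa.
#' @param tree rooted \code{phylo} covering the table's features.
#' @param references reference tip labels.
#' @return data.frame with columns sample_id, nsti.
#' @export
nstiScores <- function(x, tree, references) {
  assertFeatureTable(x)
  m <- featureCounts(x)
  if (any(colSums(m) == 0)) stop("empty sample(s) present")
  lk <- nearestReferenceLookup(tree, rownames(m), references)
  d <- lk$distance
  data.frame(
    sample_id = colnames(m),
    nsti = as.numeric(crossprod(m, d) / colSums(m)),
    stringsAsFactors = FALSE
  )
}

#' Predict a functional (KO) table from taxa by nearest-reference inheritance
#'
#' Each OTU inherits the KO copy-number vector of its nearest sequenced
#' reference taxon; the KO abundance of a sample is the copy-weighted sum of
#' its OTU abundances, rounded to integer counts. OTUs missing from the tree
#' are excluded with a message.
#'
#' @param x a taxon \linkS4class{FeatureTable}.
#' @param tree rooted \code{phylo}.
#' @param functionMap a \linkS4class{TaxonFunctionMap}.
#' @return a \linkS4class{FeatureTable} with \code{featureKind = "function"}.
#' @export
predictFunctionTable <- function(x, tree, functionMap) {
  assertFeatureTable(x)
  stopifnot(methods::is(functionMap, "TaxonFunctionMap"))
  m <- featureCounts(x)
  inTree <- rownames(m) %in% tree$tip.label
  if (any(!inTree))
    message("excluding ", sum(!inTree), " feature(s) absent from the tree")
  m <- m[inTree, , drop = FALSE]
  refs <- intersect(referenceTaxa(functionMap), colnames(koCopies(functionMap)))
  lk <- nearestReferenceLookup(tree, rownames(m), refs)
  copies <- koCopies(functionMap)[, lk$reference, drop = FALSE]
  ko <- round(copies %*% m)
  dimnames(ko) <- list(rownames(koCopies(functionMap)), colnames(m))
  FeatureTable(ko, featureKind = "function")
}

#' Functional richness
#'
#' Number of distinct KOs observed (count > 0) per sample.
#'
#' @param x a function-kind \linkS4class{FeatureTable}.
#' @return named integer vector per sample.
#' @export
functionalRichness <- function(x) {
  assertFeatureTable(x)
  if (featureKind(x) != "function")
    stop("functionalRichness expects a function-kind table")
  colSums(featureCounts(x) > 0)
}

#' Read / write a taxon-to-function map
#'
#' Long-format TSV with columns \code{taxon}, \code{ko}, \code{copies}.
#' Unlisted (taxon, ko) combinations have zero copies.
#'
#' @param path TSV path.
#' @param references reference taxon ids; defaults to all taxa in the file.
#' @return a \linkS4class{TaxonFunctionMap}.
#' @export
readTaxonFunctionMap <- function(path, references = NULL) {
  df <- utils::read.delim(path, colClasses = c("character", "character",
                                               "numeric"))
  need <- c("taxon", "ko", "copies")
  if (!all(need %in% names(df)))
    stop("map file needs columns: ", paste(need, collapse = ", "))
  taxa <- sort(unique(df$taxon))
  kos <- sort(unique(df$ko))
  m <- matrix(0, length(kos), length(taxa), dimnames = list(kos, taxa))
  m[cbind(match(df$ko, kos), match(df$taxon, taxa))] <- df$copies
  if (is.null(references)) references <- taxa
  TaxonFunctionMap(m, references = references)
}

#' @rdname readTaxonFunctionMap
#' @param map a \linkS4class{TaxonFunctionMap}.
#' @export
writeTaxonFunctionMap <- function(map, path) {
  m <- koCopies(map)
  nz <- which(m > 0, arr.ind = TRUE)
  df <- data.frame(taxon = colnames(m)[nz[, 2]],
                   ko = rownames(m)[nz[, 1]],
                   copies = m[nz])
  df <- df[order(df$taxon, df$ko), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
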