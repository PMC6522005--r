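#' FeatureTable: a features-by-samples count matrix
#'
#' Container for a microbiome feature table: non-negative integer counts of
#' taxonomic features (OTUs) or functional features (KEGG Orthology gene
#' families) across samples. Features are rows, samples are columns, matching
#' the QIIME-classic orientation.
#'
#' @slot counts numeric matrix of non-negative integer counts,
#'   features x samples, with unique dimnames.
#' @slot featureKind either \code{"taxon"} or \code{"function"}.
#' @slot taxonomy named character vector of lineage strings; may be empty.
#'   Names must be feature ids.
#'
#' @export
setClass("FeatureTable",
  representation(
    counts = "matrix",
    featureKind = "character",
    taxonomy = "character"
  ),
  prototype(
    counts = matrix(numeric(0), 0, 0),
    featureKind = "taxon",
    taxonomy = character(0)
  )
)

setValidity("FeatureTable", function(object) {
  m <- object@counts
  msgs <- character(0)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msgs <- c(msgs, "counts must have feature (row) and sample (column) names")
  else {
    if (anyDuplicated(rownames(m)))
      msgs <- c(msgs, "duplicate feature ids")
    if (anyDuplicated(colnames(m)))
      msgs <- c(msgs, "duplicate sample ids")
  }
  if (length(m)) {
    bad <- which(is.na(m) | m < 0 | abs(m - round(m)) > 1e-8, arr.ind = TRUE)
    if (nrow(bad))
      msgs <- c(msgs, sprintf(
        "counts must be non-negative integers; first offending cell [%d, %d] = %s",
        bad[1, 1], bad[1, 2], format(m[bad[1, 1], bad[1, 2]])))
  }
  if (length(object@featureKind) != 1L ||
      !object@featureKind %in% c("taxon", "function"))
    msgs <- c(msgs, "featureKind must be 'taxon' or 'function'")
  if (length(object@taxonomy) &&
      !all(names(object@taxonomy) %in% rownames(m)))
    msgs <- c(msgs, "taxonomy names must be feature ids")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureTable
#'
#' @param counts numeric matrix of non-negative integer counts
#'   (features x samples) with dimnames, or an object coercible to one.
#' @param featureKind \code{"taxon"} (OTUs) or \code{"function"} (KOs).
#' @param taxonomy optional named character vector of lineage strings.
#'
#' @return A \linkS4class{FeatureTable}.
#'
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("OTU1", "OTU2"), c("s1", "s2")))
#' ft <- FeatureTable(m)
#' sampleSums(ft)
#'
#' @export
FeatureTable <- function(counts, featureKind = "taxon",
                         taxonomy = character(0)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  new("FeatureTable", counts = counts, featureKind = featureKind,
      taxonomy = taxonomy)
}

#' @describeIn FeatureTable count matrix (features x samples)
#' @param x,object a FeatureTable
#' @export
setGeneric("featureCounts", function(x) standardGeneric("featureCounts"))

#' @rdname FeatureTable
#' @export
setMethod("featureCounts", "FeatureTable", function(x) x@counts)

#' @describeIn FeatureTable feature identifiers (row names)
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname FeatureTable
#' @export
setMethod("featureIds", "FeatureTable", function(x) rownames(x@counts))

#' @describeIn FeatureTable sample identifiers (column names)
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname FeatureTable
#' @export
setMethod("sampleIds", "FeatureTable", function(x) colnames(x@counts))

#' @describeIn FeatureTable feature kind ("taxon" or "function")
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))

#' @rdname FeatureTable
#' @export
setMethod("featureKind", "FeatureTable", function(x) x@featureKind)

#' @describeIn FeatureTable taxonomy annotations (may be empty)
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname FeatureTable
#' @export
setMethod("taxonomy", "FeatureTable", function(x) x@taxonomy)

#' @describeIn FeatureTable per-sample totals (column sums)
#' @export
setGeneric("sampleSums", function(x) standardGeneric("sampleSums"))

#' @rdname FeatureTable
#' @export
setMethod("sampleSums", "FeatureTable", function(x) colSums(x@counts))

#' @describeIn FeatureTable per-feature totals (row sums)
#' @export
setGeneric("featureSums", function(x) standardGeneric("featureSums"))

#' @rdname FeatureTable
#' @export
setMethod("featureSums", "FeatureTable", function(x) rowSums(x@counts))

#' @rdname FeatureTable
#' @param i,j feature and sample indices (integer, logical or character)
#' @param ... ignored
#' @param drop ignored; subsetting always returns a FeatureTable
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  m <- x@counts
  if (!missing(i)) m <- m[i, , drop = FALSE]
  if (!missing(j)) m <- m[, j, drop = FALSE]
  tax <- x@taxonomy
  if (length(tax)) tax <- tax[names(tax) %in% rownames(m)]
  new("FeatureTable", counts = m, featureKind = x@featureKind, taxonomy = tax)
})

setMethod("show", "FeatureTable", function(object) {
  m <- object@counts
  cat(sprintf("FeatureTable (%s): %d features x %d samples\n",
              object@featureKind, nrow(m), ncol(m)))
  if (ncol(m))
    cat(sprintf("  sample depths: %s .. %s\n",
                format(min(colSums(m))), format(max(colSums(m)))))
  if (length(object@taxonomy))
    cat(sprintf("  taxonomy: %d annotated features\n",
                length(object@taxonomy)))
})

#' CooccurrenceNetwork: a signed feature co-occurrence graph
#'
#' Undirected graph over features in which each edge is a Spearman
#' correlation between two features' within-group relative abundances that
#' passed both retention criteria (|rho| above threshold and BH-adjusted p
#' at or below alpha).
#'
#' @slot edges data.frame with columns feature_a, feature_b, rho, sign
#'   ("+"/"-"), p_raw, p_adjusted; one row per unordered pair.
#' @slot nodes character vector of feature ids with at least one edge.
#' @slot groupLabel label of the sample group the network was fit on.
#' @slot nPairsTested number of feature pairs tested (BH denominator).
#'
#' @export
setClass("CooccurrenceNetwork",
  representation(
    edges = "data.frame",
    nodes = "character",
    groupLabel = "character",
    nPairsTested = "integer"
  )
)

setValidity("CooccurrenceNetwork", function(object) {
  e <- object@edges
  need <- c("feature_a", "feature_b", "rho", "sign", "p_raw", "p_adjusted")
  msgs <- character(0)
  if (!all(need %in% names(e)))
    msgs <- c(msgs, paste("edges must have columns:", paste(need, collapse = ", ")))
  else if (nrow(e)) {
    if (any(e$feature_a == e$feature_b))
      msgs <- c(msgs, "self-edges are not allowed")
    key <- paste(pmin(e$feature_a, e$feature_b), pmax(e$feature_a, e$feature_b))
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate edges")
    if (!all(unique(c(e$feature_a, e$feature_b)) %in% object@nodes))
      msgs <- c(msgs, "every edge endpoint must be a node")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CooccurrenceNetwork edge table
#' @param x,object a CooccurrenceNetwork
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname CooccurrenceNetwork
#' @export
setMethod("networkEdges", "CooccurrenceNetwork", function(x) x@edges)

#' @describeIn CooccurrenceNetwork node ids (features with >= 1 edge)
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname CooccurrenceNetwork
#' @export
setMethod("networkNodes", "CooccurrenceNetwork", function(x) x@nodes)

#' @describeIn CooccurrenceNetwork group the network was fit on
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname CooccurrenceNetwork
#' @export
setMethod("groupLabel", "CooccurrenceNetwork", function(x) x@groupLabel)

setMethod("show", "CooccurrenceNetwork", function(object) {
  cat(sprintf("CooccurrenceNetwork [%s]: %d nodes, %d edges (%d pairs tested)\n",
              object@groupLabel, length(object@nodes), nrow(object@edges),
              object@nPairsTested))
  if (nrow(object@edges))
    cat(sprintf("  positive edges: %d, negative edges: %d\n",
                sum(object@edges$sign == "+"), sum(object@edges$sign == "-")))
})

#' TaxonFunctionMap: reference gene content for functional prediction
#'
#' Gene (KO) copy numbers for a set of "sequenced" reference taxa, the
#' knowledge base for nearest-sequenced-taxon functional prediction and
#' weighted NSTI scoring.
#'
#' @slot copies non-negative integer matrix, KOs x reference taxa.
#' @slot references character vector of reference ("sequenced") taxon ids;
#'   must contain all column names of \code{copies}.
#'
#' @export
setClass("TaxonFunctionMap",
  representation(copies = "matrix", references = "character")
)

setValidity("TaxonFunctionMap", function(object) {
  m <- object@copies
  msgs <- character(0)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msgs <- c(msgs, "copies must have KO (row) and taxon (column) names")
  if (length(m) && (any(m < 0) || any(abs(m - round(m)) > 1e-8)))
    msgs <- c(msgs, "copy numbers must be non-negative integers")
  if (!all(colnames(m) %in% object@references))
    msgs <- c(msgs, "every mapped taxon must be listed as a reference")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TaxonFunctionMap
#'
#' @param copies non-negative integer matrix (KOs x reference taxa) with
#'   dimnames.
#' @param references character vector of reference taxon ids; defaults to the
#'   column names of \code{copies}.
#'
#' @return A \linkS4class{TaxonFunctionMap}.
#' @export
TaxonFunctionMap <- function(copies, references = colnames(copies)) {
  copies <- as.matrix(copies)
  storage.mode(copies) <- "double"
  new("TaxonFunctionMap", copies = copies, references = references)
}

#' @describeIn TaxonFunctionMap KO copy-number matrix
#' @param x,object a TaxonFunctionMap
#' @export
setGeneric("koCopies", function(x) standardGeneric("koCopies"))

#' @rdname TaxonFunctionMap
#' @export
setMethod("koCopies", "TaxonFunctionMap", function(x) x@copies)

#' @describeIn TaxonFunctionMap reference taxon ids
#' @export
setGeneric("referenceTaxa", function(x) standardGeneric("referenceTaxa"))

#' @rdname TaxonFunctionMap
#' @export
setMethod("referenceTaxa", "TaxonFunctionMap", function(x) x@references)

setMethod("show", "TaxonFunctionMap", function(object) {
  cat(sprintf("TaxonFunctionMap: %d KOs x %d reference taxa\n",
              nrow(object@copies), ncol(object@copies)))
})
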