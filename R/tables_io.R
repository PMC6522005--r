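#' Read a feature table from TSV or classic-BIOM JSON
#'
#' TSV tables use the QIIME-classic dialect: features as rows, samples as
#' columns, first header cell \code{"#OTU ID"} (or \code{"#KO ID"} for
#' function tables). A leading header cell of \code{"#Sample ID"} marks a
#' transposed (samples-as-rows) table, which is flipped on read. Classic-BIOM
#' JSON is read through \pkg{biomformat} and supports both \code{"dense"} and
#' \code{"sparse"} \code{matrix_type}.
#'
#' @param path path to the table file.
#' @param format \code{"tsv"} or \code{"biom_classic_json"}.
#' @param featureKind \code{"taxon"} or \code{"function"}.
#' @return A \linkS4class{FeatureTable}.
#'
#' @export
readFeatureTable <- function(path, format = c("tsv", "biom_classic_json"),
                             featureKind = "taxon") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    lines <- readLines(path)
    hdr_idx <- max(c(1L, which(startsWith(lines, "#"))))
    if (hdr_idx >= length(lines)) stop("no data rows in ", path)
    header <- strsplit(sub("^#", "", lines[hdr_idx]), "\t", fixed = TRUE)[[1]]
    body <- utils::read.delim(text = lines[(hdr_idx + 1L):length(lines)],
                              header = FALSE, sep = "\t",
                              colClasses = c("character",
                                             rep("numeric", length(header) - 1L)))
    ids <- body[[1]]
    if (anyDuplicated(ids))
      stop("duplicate feature ids in ", path, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(body[, -1, drop = FALSE])
    dimnames(m) <- list(ids, header[-1])
    if (trimws(header[1]) == "Sample ID") m <- t(m)
  } else {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
  }
  FeatureTable(m, featureKind = featureKind)
}

#' Write a feature table to TSV or classic-BIOM JSON
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param path output file path.
#' @param format \code{"tsv"} (QIIME-classic, \code{"#OTU ID"} header) or
#'   \code{"biom_classic_json"}.
#' @return \code{path}, invisibly.
#'
#' @export
writeFeatureTable <- function(x, path,
                              format = c("tsv", "biom_classic_json")) {
  assertFeatureTable(x)
  format <- match.arg(format)
  m <- featureCounts(x)
  if (format == "tsv") {
    idcol <- if (featureKind(x) == "function") "#KO ID" else "#OTU ID"
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c(idcol, colnames(m)), collapse = "\t"), con)
    utils::write.table(
      cbind(rownames(m), format(m, scientific = FALSE, trim = TRUE)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    biomformat::write_biom(biomformat::make_biom(m), path)
  }
  invisible(path)
}

#' Read sample metadata
#'
#' Metadata TSV must contain columns \code{sample_id}, \code{genotype},
#' \code{zygosity} and \code{cage}. Zygosity must be \code{"homozygote"} or
#' \code{"heterozygote"} and must be constant within genotype (it is a
#' deterministic function of the genotype label).
#'
#' @param path path to a metadata TSV.
#' @return data.frame with one row per sample.
#' @export
readSampleMetadata <- function(path) {
  md <- utils::read.delim(path, colClasses = "character")
  need <- c("sample_id", "genotype", "zygosity", "cage")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  validateSampleMetadata(md)
}

validateSampleMetadata <- function(md) {
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample ids in metadata")
  if (!all(md$zygosity %in% c("homozygote", "heterozygote")))
    stop("zygosity must be 'homozygote' or 'heterozygote'")
  byg <- tapply(md$zygosity, md$genotype, function(z) length(unique(z)))
  if (any(byg > 1))
    stop("zygosity is not constant within genotype: ",
         paste(names(byg)[byg > 1], collapse = ", "))
  md
}

#' @rdname readSampleMetadata
#' @param md metadata data.frame.
#' @export
writeSampleMetadata <- function(md, path) {
  validateSampleMetadata(md)
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Check that every table sample has exactly one metadata row.
matchMetadata <- function(x, md) {
  miss <- setdiff(sampleIds(x), md$sample_id)
  if (length(miss))
    stop("samples without metadata: ", paste(miss, collapse = ", "))
  md[match(sampleIds(x), md$sample_id), , drop = FALSE]
}

#' Read / write rooted newick trees
#'
#' Thin validating wrappers around \pkg{ape}. Trees must be rooted, have
#' unique tip labels and non-negative branch lengths.
#'
#' @param path newick file path.
#' @return \code{readTree}: an \code{ape::phylo}.
#' @export
readTree <- function(path) {
  tr <- ape::read.tree(path)
  validateTree(tr)
}

validateTree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo tree")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  if (is.null(tr$edge.length) || any(tr$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  tr
}

#' @rdname readTree
#' @param tr an \code{ape::phylo} tree.
#' @export
writeTree <- function(tr, path) {
  validateTree(tr)
  ape::write.tree(tr, path)
  invisible(path)
}

#' Remove singleton features
#'
#' Drops features whose total count across all samples equals exactly 1
#' (likely sequencing errors); all other features are kept unchanged.
#' Idempotent.
#'
#' @param x a \linkS4class{FeatureTable}.
#' @return the filtered \linkS4class{FeatureTable}.
#' @export
removeSingletons <- function(x) {
  assertFeatureTable(x)
  keep <- featureSums(x) != 1
  x[keep, ]
}

#' Rarefy samples to a fixed depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly \code{depth} reads. Samples with fewer than
#' \code{depth} total reads are dropped with a message. Reproducible under
#' \code{seed}.
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param depth target reads per sample (default 16000).
#' @param seed optional integer seed.
#' @return the rarefied \linkS4class{FeatureTable}; every retained sample
#'   sums to exactly \code{depth}.
#' @export
rarefy <- function(x, depth = 16000, seed = NULL) {
  assertFeatureTable(x)
  if (length(depth) != 1L || is.na(depth) || depth < 1)
    stop("depth must be a positive integer")
  depth <- as.integer(depth)
  totals <- sampleSums(x)
  drop <- totals < depth
  if (any(drop))
    message("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(sampleIds(x)[drop], collapse = ", "))
  x <- x[, !drop]
  if (!ncol(featureCounts(x))) return(x)
  withSeed(seed, {
    # vegan warns whenever the smallest nonzero count exceeds 1; harmless here
    sub <- withCallingHandlers(
      t(vegan::rrarefy(t(featureCounts(x)), depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    new("FeatureTable", counts = sub, featureKind = x@featureKind,
        taxonomy = x@taxonomy)
  })
}
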