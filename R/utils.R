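# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL means "use the current stream".
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

assertFeatureTable <- function(x) {
  if (!methods::is(x, "FeatureTable"))
    stop("expected a FeatureTable, got ", class(x)[1])
  methods::validObject(x)
  invisible(x)
}

# group vector aligned to the table's samples: named vector or factor
alignGroups <- function(groups, sample_ids) {
  if (!is.null(names(groups))) {
    missing <- setdiff(sample_ids, names(groups))
    if (length(missing))
      stop("no group label for sample(s): ", paste(missing, collapse = ", "))
    groups <- groups[sample_ids]
  } else if (length(groups) != length(sample_ids)) {
    stop("groups must be named by sample id or have one entry per sample")
  }
  as.character(groups)
}

# off-diagonal lower-triangle values of a symmetric matrix / dist
lowerTri <- function(d) {
  m <- as.matrix(d)
  m[lower.tri(m)]
}
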