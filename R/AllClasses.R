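#' ExpressionMatrix: expression values with phenotype and batch labels
#'
#' A thin [SummarizedExperiment::SummarizedExperiment-class] subclass holding
#' a single `exprs` assay (log2-intensity scale, features in rows, samples in
#' columns) together with mandatory `phenotype` and `batch` columns in
#' `colData`. Feature and sample identifiers must be unique and the matrix
#' must be finite.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [ExpressionMatrix()] for the constructor,
#'   [generateExpression()] for synthetic data.
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

.validExpressionMatrix <- function(object) {
  msg <- character()
  if (!identical(SummarizedExperiment::assayNames(object), "exprs"))
    msg <- c(msg, "assays must be exactly one assay named 'exprs'")
  else {
    v <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(v)) msg <- c(msg, "'exprs' must be numeric")
    else if (any(!is.finite(v))) msg <- c(msg, "'exprs' contains non-finite values")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("phenotype", "batch") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'phenotype' and 'batch'")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if (length(msg)) msg else TRUE
}
setValidity("ExpressionMatrix", .validExpressionMatrix)

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids).
#' @param phenotype character vector of phenotype labels, one per sample.
#' @param batch character vector of batch labels, one per sample (a single
#'   batch label is recycled).
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(20), 5, 4,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' em <- ExpressionMatrix(m, phenotype = rep(c("A", "B"), 2), batch = "b1")
#' phenotypeLabels(em)
#' @export
ExpressionMatrix <- function(values, phenotype, batch = "batch1") {
  stopifnot(is.matrix(values))
  if (length(batch) == 1L) batch <- rep(batch, ncol(values))
  if (length(phenotype) != ncol(values) || length(batch) != ncol(values))
    stop("'phenotype' and 'batch' must have one label per sample")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(phenotype = as.character(phenotype),
                                   batch = as.character(batch),
                                   row.names = colnames(values)))
  methods::new("ExpressionMatrix", se)
}

#' @rdname phenotypeLabels
#' @export
setMethod("phenotypeLabels", "ExpressionMatrix", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$phenotype, colnames(x))
})

#' @rdname batchLabels
#' @export
setMethod("batchLabels", "ExpressionMatrix", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$batch, colnames(x))
})

#' @rdname featureIds
#' @export
setMethod("featureIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' @rdname exprsValues
#' @export
setMethod("exprsValues", "ExpressionMatrix", function(x)
  SummarizedExperiment::assay(x, "exprs"))

#' GeneNetwork: a simple undirected weighted graph on gene symbols
#'
#' Edges are stored as a canonical data.frame (`source < target` under C
#' collation, no self-loops, no duplicates, rows sorted by source then
#' target). Nodes exist only through edges: the inference construction never
#' produces isolated nodes, and the node set is derived from the edge
#' endpoints.
#'
#' @slot edges data.frame with columns `source`, `target`, `weight`.
#' @seealso [buildNetwork()], [computeMetrics()], [giantComponent()]
#' @export
setClass("GeneNetwork", representation(edges = "data.frame"))

.validGeneNetwork <- function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("source", "target", "weight") %in% colnames(e)))
    return("edges must have columns source, target, weight")
  if (nrow(e)) {
    if (any(e$source == e$target)) msg <- c(msg, "self-loops are not allowed")
    key <- paste(e$source, e$target, sep = "|")
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges are not allowed")
    swapped <- mapply(function(a, b) .chr_lt(b, a), e$source, e$target)
    if (any(swapped)) msg <- c(msg, "edges must satisfy source < target")
    if (!is.numeric(e$weight)) msg <- c(msg, "weights must be numeric")
  }
  if (length(msg)) msg else TRUE
}
setValidity("GeneNetwork", .validGeneNetwork)

#' @rdname nodeSet
#' @export
setMethod("nodeSet", "GeneNetwork", function(x)
  .chr_sort(unique(c(x@edges$source, x@edges$target))))

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "GeneNetwork", function(x) x@edges)

#' @rdname edgeKeys
#' @export
setMethod("edgeKeys", "GeneNetwork", function(x)
  if (nrow(x@edges)) paste(x@edges$source, x@edges$target, sep = "|")
  else character())

#' @rdname numNodes
#' @export
setMethod("numNodes", "GeneNetwork", function(x) length(nodeSet(x)))

#' @rdname numEdges
#' @export
setMethod("numEdges", "GeneNetwork", function(x) nrow(x@edges))

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork with", numNodes(object), "nodes and",
      numEdges(object), "edges\n")
  if (numEdges(object)) {
    w <- object@edges$weight
    cat(sprintf("  weight (MI, nats): min %.4g, max %.4g\n", min(w), max(w)))
  }
})

#' MINull: pooled permutation null for MI significance
#'
#' Holds the pooled permutation MI values (sorted ascending), the sample
#' size they were computed at, and the coefficients of an exponential tail
#' fit (log survival ~ intercept + slope * MI on the upper tail) used to
#' extrapolate p-values below the empirical resolution 1/pool size.
#'
#' @slot pooled sorted numeric vector of permutation MI values.
#' @slot sample_size number of samples per profile.
#' @slot n_permutations permutations per sampled pair.
#' @slot n_pairs number of feature pairs sampled.
#' @slot tail_intercept,tail_slope exponential tail fit (slope < 0).
#' @slot tail_fraction upper fraction of the pool used for the fit.
#' @slot seed RNG seed used to build the null.
#' @seealso [buildNull()], [pValue()], [miThreshold()]
#' @export
setClass("MINull", representation(
  pooled = "numeric", sample_size = "integer", n_permutations = "integer",
  n_pairs = "integer", tail_intercept = "numeric", tail_slope = "numeric",
  tail_fraction = "numeric", seed = "integer"))

.validMINull <- function(object) {
  msg <- character()
  if (is.unsorted(object@pooled)) msg <- c(msg, "pooled values must be sorted")
  if (length(object@pooled) < 100) msg <- c(msg, "pool must hold >= 100 values")
  if (!is.na(object@tail_slope) && object@tail_slope >= 0)
    msg <- c(msg, "tail slope must be negative (survival decreasing in MI)")
  if (length(msg)) msg else TRUE
}
setValidity("MINull", .validMINull)

setMethod("show", "MINull", function(object) {
  cat("MINull:", length(object@pooled), "pooled permutation MI values",
      sprintf("(%d pairs x %d permutations, n = %d)\n",
              object@n_pairs, object@n_permutations, object@sample_size))
  cat(sprintf("  tail fit: log S(mi) = %.3f %+.3f * mi (upper %.0f%%)\n",
              object@tail_intercept, object@tail_slope,
              100 * object@tail_fraction))
})
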