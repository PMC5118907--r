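#' @title Generics for phenonet data classes
#' @name phenonet-generics
#' @keywords internal
NULL

#' Phenotype label per sample
#'
#' @param x an [ExpressionMatrix-class] object.
#' @return Named character vector, one label per sample.
#' @export
setGeneric("phenotypeLabels", function(x) standardGeneric("phenotypeLabels"))

#' Batch label per sample
#'
#' @param x an [ExpressionMatrix-class] object.
#' @return Named character vector, one label per sample.
#' @export
setGeneric("batchLabels", function(x) standardGeneric("batchLabels"))

#' Feature identifiers
#'
#' @param x an [ExpressionMatrix-class] object.
#' @return Character vector of probe/gene identifiers (matrix rows).
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' Sample identifiers
#'
#' @param x an [ExpressionMatrix-class] object.
#' @return Character vector of sample identifiers (matrix columns).
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Expression values
#'
#' @param x an [ExpressionMatrix-class] object.
#' @return Numeric matrix, features in rows, samples in columns.
#' @export
setGeneric("exprsValues", function(x) standardGeneric("exprsValues"))

#' Node set of a network
#'
#' @param x a [GeneNetwork-class] object.
#' @return Character vector of node (gene) labels, sorted.
#' @export
setGeneric("nodeSet", function(x) standardGeneric("nodeSet"))

#' Edge table of a network
#'
#' @param x a [GeneNetwork-class] object.
#' @return A data.frame with columns `source`, `target` (source < target)
#'   and `weight` (mutual information, nats).
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Canonical edge keys of a network
#'
#' Each undirected edge is encoded as `"a|b"` with `a < b`, so edge sets of
#' different networks can be compared as plain string sets.
#'
#' @param x a [GeneNetwork-class] object.
#' @return Character vector of `"a|b"` keys.
#' @export
setGeneric("edgeKeys", function(x) standardGeneric("edgeKeys"))

#' Number of nodes
#' @param x a [GeneNetwork-class] object.
#' @return Integer scalar.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' Number of edges
#' @param x a [GeneNetwork-class] object.
#' @return Integer scalar.
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Permutation-null p-value of an MI value
#'
#' @param null a [MINull-class] permutation null model.
#' @param mi numeric vector of MI values (nats).
#' @return Numeric vector of p-values in (0, 1].
#' @export
setGeneric("pValue", function(null, mi) standardGeneric("pValue"))

#' MI threshold at a significance level
#'
#' Smallest MI whose null survival probability is at most `p`. Within the
#' empirical resolution of the pooled null the empirical quantile is used;
#' below it (e.g. p = 1e-10) the fitted exponential tail is extrapolated.
#'
#' @param null a [MINull-class] permutation null model.
#' @param p significance level in (0, 1].
#' @return MI threshold in nats (0 when `p >= 1`).
#' @export
setGeneric("miThreshold", function(null, p) standardGeneric("miThreshold"))
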