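#' Jaccard index of two sets
#'
#' |A intersect B| / |A union B|. Defined as 1 when both sets are empty
#' (identical sets), with a warning.
#'
#' @param a,b character vectors treated as sets (duplicates ignored).
#' @return Fraction in [0, 1].
#' @examples jaccard(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) {
    warning("both sets empty; Jaccard defined as 1")
    return(1)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Node- and edge-set Jaccard matrices across networks
#'
#' Node similarity is computed on gene symbols, edge similarity on
#' unordered symbol pairs (weights ignored). Order-invariant; both matrices
#' are symmetric with unit diagonal.
#'
#' @param networks named list (unique labels) of >= 2
#'   [GeneNetwork-class] objects.
#' @return A list with `node_jaccard` and `edge_jaccard` matrices
#'   (labels as dimnames).
#' @export
jaccardMatrices <- function(networks) {
  labels <- names(networks)
  if (length(networks) < 2) stop("need at least 2 networks")
  if (is.null(labels) || anyDuplicated(labels))
    stop("networks must carry unique labels")
  nodes <- lapply(networks, nodeSet)
  edges <- lapply(networks, edgeKeys)
  k <- length(networks)
  mk <- function(sets) {
    m <- diag(1, k)
    dimnames(m) <- list(labels, labels)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      m[i, j] <- m[j, i] <- jaccard(sets[[i]], sets[[j]])
    m
  }
  list(node_jaccard = mk(nodes), edge_jaccard = mk(edges))
}

#' Venn partition of labeled sets
#'
#' Assigns each element of the union to exactly one region: the subset of
#' labels whose sets contain it. All 2^k - 1 regions are reported (k = 2..6
#' sets), so region counts sum to the union size.
#'
#' @param node_sets named list of 2 to 6 character vectors.
#' @return A list with `counts` (named integer over all regions; region
#'   names join member labels with `&`) and `members` (gene lists per
#'   region).
#' @export
vennPartition <- function(node_sets) {
  k <- length(node_sets)
  if (k < 2 || k > 6)
    stop("venn partition supports 2 to 6 sets, got ", k)
  labels <- names(node_sets)
  if (is.null(labels) || anyDuplicated(labels))
    stop("sets must carry unique labels")
  node_sets <- lapply(node_sets, unique)
  universe <- unique(unlist(node_sets))
  membership <- vapply(node_sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1)
  region_names <- apply(membership, 1, function(m)
    paste(labels[m], collapse = "&"))
  all_regions <- unlist(lapply(seq_len(k), function(size)
    utils::combn(labels, size, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(all_regions)), all_regions)
  tab <- table(region_names)
  counts[names(tab)] <- as.integer(tab)
  members <- lapply(stats::setNames(all_regions, all_regions), function(r)
    .chr_sort(universe[region_names == r]))
  list(counts = counts, members = members)
}

#' Core gene set
#'
#' Genes present in every "case" (e.g. cancer-subtype) network but absent
#' from a reference (e.g. non-tumor) set:
#' (intersection of `case_sets`) minus `reference_set`.
#'
#' @param case_sets named list of >= 1 character vectors.
#' @param reference_set character vector (may be empty: plain intersection).
#' @return Character vector, sorted.
#' @export
coreSet <- function(case_sets, reference_set = character()) {
  if (!length(case_sets)) stop("need at least one case set")
  core <- Reduce(intersect, lapply(case_sets, unique))
  .chr_sort(setdiff(core, reference_set))
}

#' Induced subgraph on a gene set
#'
#' Keeps edges with both endpoints inside `genes`. Genes absent from the
#' network are silently excluded and reported in the `"absent"` attribute
#' of the result.
#'
#' @param net a [GeneNetwork-class] object.
#' @param genes character vector of gene labels.
#' @return A [GeneNetwork-class]; `attr(result, "absent")` lists requested
#'   genes not present in `net`.
#' @export
inducedSubgraph <- function(net, genes) {
  e <- net@edges
  keep <- e$source %in% genes & e$target %in% genes
  out <- .network_from_edges(e[keep, , drop = FALSE])
  attr(out, "absent") <- .chr_sort(setdiff(genes, nodeSet(net)))
  out
}

#' Degree of genes across networks
#'
#' @param networks named list of [GeneNetwork-class] objects.
#' @param genes character vector of genes of interest.
#' @return Integer matrix genes x networks of degrees (0 when absent);
#'   `attr(result, "absent")` is a logical matrix flagging genes absent
#'   from each network.
#' @export
crossNetworkDegree <- function(networks, genes) {
  labels <- names(networks)
  if (is.null(labels) || anyDuplicated(labels))
    stop("networks must carry unique labels")
  genes <- unique(genes)
  deg <- matrix(0L, length(genes), length(networks),
                dimnames = list(genes, labels))
  absent <- matrix(TRUE, length(genes), length(networks),
                   dimnames = list(genes, labels))
  for (l in labels) {
    d <- igraph::degree(.as_igraph(networks[[l]]))
    hit <- genes %in% names(d)
    deg[hit, l] <- as.integer(d[genes[hit]])
    absent[hit, l] <- FALSE
  }
  attr(deg, "absent") <- absent
  deg
}
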