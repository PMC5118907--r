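# Graph primitives are delegated to igraph behind this module's surface;
# the GeneNetwork container keeps a canonical, locale-independent edge table
# so results are reproducible and comparable as plain sets.

.as_igraph <- function(net) {
  e <- net@edges
  if (!nrow(e))
    return(igraph::make_empty_graph(0, directed = FALSE))
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  g
}

.network_from_edges <- function(edges) {
  edges <- edges[.chr_order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  methods::new("GeneNetwork", edges = edges)
}

#' Build a gene network from scored interactions
#'
#' Constructs a simple undirected weighted graph: duplicate unordered pairs
#' are collapsed keeping the maximum weight; self-pairs are rejected with an
#' error naming the offenders (the probe collapse step should have removed
#' them).
#'
#' @param edges data.frame of interactions; the first two columns are the
#'   endpoints (e.g. `feature_a`/`feature_b` or `source`/`target`), and an
#'   `mi` or `weight` column carries the weight (defaults to 1 if absent).
#' @return A [GeneNetwork-class] object.
#' @examples
#' net <- buildNetwork(data.frame(feature_a = c("a", "b"),
#'                                feature_b = c("b", "c"), mi = c(1, 2)))
#' numNodes(net); numEdges(net)
#' @export
buildNetwork <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0)
    return(.network_from_edges(data.frame(source = character(),
                                          target = character(),
                                          weight = numeric(),
                                          stringsAsFactors = FALSE)))
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  w <- if ("mi" %in% colnames(edges)) edges$mi
       else if ("weight" %in% colnames(edges)) edges$weight
       else rep(1, nrow(edges))
  if (any(a == b))
    stop("self-pairs present: ",
         paste(unique(a[a == b]), collapse = ", "))
  src <- .chr_pmin(a, b); tgt <- .chr_pmax(a, b)
  key <- paste(src, tgt, sep = "|")
  o <- order(-w, method = "radix")
  first <- o[!duplicated(key[o])]   # keep max weight per unordered pair
  .network_from_edges(data.frame(source = src[first], target = tgt[first],
                                 weight = w[first],
                                 stringsAsFactors = FALSE))
}

.mean_local_cc <- function(g, include_low_degree = TRUE) {
  if (igraph::vcount(g) == 0) return(0)
  cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  if (include_low_degree) {
    cc[is.nan(cc)] <- 0            # degree < 2 contributes 0 to the mean
    mean(cc)
  } else {
    cc <- cc[!is.nan(cc)]
    if (!length(cc)) 0 else mean(cc)
  }
}

#' Topology metrics of a gene network
#'
#' Node and edge counts, the connected-component census, both clustering
#' coefficient conventions, the node-to-link ratio and the degree table.
#' Two clustering coefficients are reported: the mean local clustering
#' coefficient, where nodes of degree < 2 contribute 0 and are included in
#' the mean (the headline value, matching what interactive network tools
#' report), and the transitivity, 3 x triangles / connected triples. Set
#' `include_low_degree = FALSE` to exclude degree < 2 nodes from the local
#' mean instead.
#'
#' @param net a [GeneNetwork-class] object.
#' @param include_low_degree include degree < 2 nodes (as 0) in the mean
#'   local clustering coefficient.
#' @return A `"NetworkMetrics"` list: `n_nodes`, `n_edges`,
#'   `n_components`, `component_sizes` (sorted descending),
#'   `giant_nodes`, `giant_edges`, `giant_fraction`,
#'   `clustering_coefficient_mean_local`, `clustering_coefficient_transitivity`,
#'   `node_link_ratio`, `degree` (named, sorted by node label).
#' @export
computeMetrics <- function(net, include_low_degree = TRUE) {
  g <- .as_igraph(net)
  nn <- igraph::vcount(g); ne <- igraph::ecount(g)
  if (nn == 0) {
    out <- list(n_nodes = 0L, n_edges = 0L, n_components = 0L,
                component_sizes = integer(), giant_nodes = 0L,
                giant_edges = 0L, giant_fraction = NA_real_,
                clustering_coefficient_mean_local = 0,
                clustering_coefficient_transitivity = 0,
                node_link_ratio = NA_real_, degree = integer())
    class(out) <- c("NetworkMetrics", "list")
    return(out)
  }
  comp <- igraph::components(g)
  sizes <- sort(comp$csize, decreasing = TRUE)
  giant <- giantComponent(net)
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- 0
  deg <- igraph::degree(g)
  deg <- stats::setNames(as.integer(deg), names(deg))
  deg <- deg[.chr_order(names(deg))]
  out <- list(
    n_nodes = as.integer(nn), n_edges = as.integer(ne),
    n_components = as.integer(comp$no),
    component_sizes = as.integer(sizes),
    giant_nodes = numNodes(giant),
    giant_edges = numEdges(giant),
    giant_fraction = numNodes(giant) / nn,
    clustering_coefficient_mean_local =
      .mean_local_cc(g, include_low_degree),
    clustering_coefficient_transitivity = trans,
    node_link_ratio = nn / ne,
    degree = deg)
  class(out) <- c("NetworkMetrics", "list")
  out
}

#' @export
print.NetworkMetrics <- function(x, ...) {
  cat(sprintf(
    "NetworkMetrics: %d nodes, %d edges, %d components\n",
    x$n_nodes, x$n_edges, x$n_components))
  cat(sprintf("  giant component: %d nodes (%.1f%%), %d edges\n",
              x$giant_nodes, 100 * x$giant_fraction, x$giant_edges))
  cat(sprintf("  clustering: mean local %.4f, transitivity %.4f; node/link %.4f\n",
              x$clustering_coefficient_mean_local,
              x$clustering_coefficient_transitivity, x$node_link_ratio))
  invisible(x)
}

#' Largest connected component
#'
#' The component with the most nodes; ties are broken by larger edge count,
#' then by the lexicographically smallest node label (deterministic).
#'
#' @param net a nonempty [GeneNetwork-class] object.
#' @return The giant component as a [GeneNetwork-class].
#' @export
giantComponent <- function(net) {
  if (numNodes(net) == 0) stop("network is empty")
  g <- .as_igraph(net)
  comp <- igraph::components(g)
  e <- net@edges
  memb <- comp$membership[e$source]   # edges live within one component
  edge_counts <- tabulate(memb, nbins = comp$no)
  node_counts <- comp$csize
  min_label <- vapply(seq_len(comp$no), function(ci)
    .chr_sort(names(comp$membership)[comp$membership == ci])[1],
    character(1))
  o <- order(-node_counts, -edge_counts, min_label, method = "radix")
  winner <- o[1]
  .network_from_edges(e[memb == winner, , drop = FALSE])
}

#' Degree-ranked hub genes
#'
#' @param net a [GeneNetwork-class] object.
#' @param top_n number of genes to report (>= 1); truncated to the node
#'   count.
#' @return data.frame `gene`, `degree`, sorted by descending degree, ties
#'   by gene label.
#' @export
hubRanking <- function(net, top_n) {
  if (top_n < 1) stop("'top_n' must be >= 1")
  g <- .as_igraph(net)
  deg <- igraph::degree(g)
  o <- order(-deg, names(deg), method = "radix")
  o <- o[seq_len(min(top_n, length(o)))]
  data.frame(gene = names(deg)[o], degree = as.integer(deg[o]),
             stringsAsFactors = FALSE)
}

#' Ego network of a gene
#'
#' Induced subgraph on a gene and its first neighbors.
#'
#' @param net a [GeneNetwork-class] object.
#' @param gene a node label present in the network.
#' @return A [GeneNetwork-class] object.
#' @export
egoNetwork <- function(net, gene) {
  if (!gene %in% nodeSet(net))
    stop("gene '", gene, "' is not in the network")
  e <- net@edges
  nbrs <- c(e$target[e$source == gene], e$source[e$target == gene])
  keep_nodes <- c(gene, nbrs)
  keep <- e$source %in% keep_nodes & e$target %in% keep_nodes
  .network_from_edges(e[keep, , drop = FALSE])
}
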