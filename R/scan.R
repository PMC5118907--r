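#' Log-spaced cutoff grid
#'
#' @param k_min,k_max grid endpoints (counts, >= 1).
#' @param length_out number of grid points before deduplication.
#' @return Strictly increasing integer vector of cutoffs.
#' @export
logGrid <- function(k_min, k_max, length_out = 20) {
  if (k_min < 1 || k_max < k_min) stop("need 1 <= k_min <= k_max")
  unique(round(exp(seq(log(k_min), log(k_max), length.out = length_out))))
}

#' Scan edge-count cutoffs
#'
#' For each cutoff K in the grid, the network is built from the K
#' highest-MI interactions ([selectTopK()]), collapsed to gene symbols when
#' a probe map is supplied, and its topology metrics are computed. Because
#' the grid shares one fixed ranking, the edge sets at successive cutoffs
#' are nested (asserted).
#'
#' @param interactions data.frame from [allPairsMI()] (nonempty).
#' @param k_grid strictly increasing integer cutoffs (>= 1). Cutoffs beyond
#'   the available pairs are truncated to the maximum.
#' @param map optional probe-to-gene map for [collapseToGenes()].
#' @return A `"ScanResult"` list: `table` (one row per K: K, node/edge
#'   counts, components, clustering coefficients, node-to-link ratio),
#'   `networks` (list of [GeneNetwork-class] per K), `k_grid`.
#' @export
scanCutoffs <- function(interactions, k_grid, map = NULL) {
  if (is.null(interactions) || !nrow(interactions))
    stop("empty interaction list")
  if (any(k_grid < 1) || is.unsorted(k_grid, strictly = TRUE))
    stop("'k_grid' must be strictly increasing counts >= 1")
  k_grid <- as.integer(pmin(k_grid, nrow(interactions)))
  k_grid <- unique(k_grid)
  ranked <- selectTopK(interactions, nrow(interactions))
  networks <- vector("list", length(k_grid))
  rows <- vector("list", length(k_grid))
  prev_keys <- character()
  for (i in seq_along(k_grid)) {
    K <- k_grid[i]
    sel <- ranked[seq_len(K), , drop = FALSE]
    if (!is.null(map)) sel <- collapseToGenes(sel, map)
    net <- buildNetwork(sel)
    keys <- edgeKeys(net)
    if (!all(prev_keys %in% keys))
      stop("internal error: cutoff networks are not nested")
    prev_keys <- keys
    m <- computeMetrics(net)
    networks[[i]] <- net
    rows[[i]] <- data.frame(
      k = K, n_nodes = m$n_nodes, n_edges = m$n_edges,
      n_components = m$n_components,
      cc_mean_local = m$clustering_coefficient_mean_local,
      cc_transitivity = m$clustering_coefficient_transitivity,
      node_link_ratio = m$node_link_ratio)
  }
  names(networks) <- as.character(k_grid)
  out <- list(table = do.call(rbind, rows), networks = networks,
              k_grid = k_grid)
  class(out) <- c("ScanResult", "list")
  out
}

#' Select a cutoff by node-to-link ratio
#'
#' The grid cutoff whose node-to-link ratio is nearest to `target_ratio`
#' (around 0.1 for biological complex networks); ties go to the smaller K.
#'
#' @param scan a `"ScanResult"` from [scanCutoffs()].
#' @param target_ratio positive target node-to-link ratio.
#' @return The selected cutoff K (integer).
#' @export
selectByRatio <- function(scan, target_ratio = 0.1) {
  stopifnot(inherits(scan, "ScanResult"))
  if (target_ratio <= 0) stop("'target_ratio' must be positive")
  d <- abs(scan$table$node_link_ratio - target_ratio)
  scan$table$k[order(d, scan$table$k)[1]]
}

#' Stability of networks across a cutoff band
#'
#' Quantifies how stable the inferred architecture is inside a band of
#' cutoffs around a selected K: per-metric range and coefficient of
#' variation, and for every band cutoff the node/edge Jaccard and the
#' Spearman correlation of node degrees (over genes shared with the
#' selected-K network) against the selected-K network.
#'
#' @param scan a `"ScanResult"` from [scanCutoffs()].
#' @param band length-2 numeric, K interval; must lie within the grid range.
#' @param k_selected reference cutoff; defaults to [selectByRatio()] at 0.1.
#' @return A list: `per_k` (data.frame: k, node_jaccard, edge_jaccard,
#'   degree_spearman), `min_node_jaccard`, `min_edge_jaccard`,
#'   `min_degree_spearman`, `metric_ranges` (per metric: min, max, cv).
#' @export
stabilityReport <- function(scan, band, k_selected = NULL) {
  stopifnot(inherits(scan, "ScanResult"))
  if (length(band) != 2 || band[1] > band[2])
    stop("'band' must be an interval c(lo, hi)")
  if (band[1] < min(scan$k_grid) || band[2] > max(scan$k_grid))
    stop("band lies outside the scan grid range [",
         min(scan$k_grid), ", ", max(scan$k_grid), "]")
  if (is.null(k_selected)) k_selected <- selectByRatio(scan)
  ref <- scan$networks[[as.character(k_selected)]]
  if (is.null(ref)) stop("k_selected is not a grid cutoff")
  ref_deg <- igraph::degree(.as_igraph(ref))
  in_band <- scan$k_grid >= band[1] & scan$k_grid <= band[2]
  if (!any(in_band)) stop("no grid cutoffs inside the band")
  ks <- scan$k_grid[in_band]
  per_k <- do.call(rbind, lapply(ks, function(K) {
    net <- scan$networks[[as.character(K)]]
    deg <- igraph::degree(.as_igraph(net))
    shared <- intersect(names(deg), names(ref_deg))
    rho <- if (length(shared) >= 3)
      stats::cor(deg[shared], ref_deg[shared], method = "spearman") else NA
    data.frame(k = K,
               node_jaccard = jaccard(nodeSet(net), nodeSet(ref)),
               edge_jaccard = jaccard(edgeKeys(net), edgeKeys(ref)),
               degree_spearman = rho)
  }))
  tab <- scan$table[in_band, , drop = FALSE]
  metrics <- c("n_nodes", "n_edges", "n_components", "cc_mean_local",
               "cc_transitivity", "node_link_ratio")
  ranges <- t(vapply(metrics, function(m) {
    v <- tab[[m]]
    c(min = min(v), max = max(v),
      cv = if (mean(v) == 0) 0 else stats::sd(v) / mean(v))
  }, numeric(3)))
  list(per_k = per_k,
       k_selected = k_selected,
       min_node_jaccard = min(per_k$node_jaccard),
       min_edge_jaccard = min(per_k$edge_jaccard),
       min_degree_spearman = min(per_k$degree_spearman, na.rm = TRUE),
       metric_ranges = ranges)
}

#' Random-graph baselines for an observed network
#'
#' Two seeded ensembles matched to the observed network: (a) uniform random
#' graphs with identical node and edge counts, (b) degree-preserving
#' rewirings of the observed network (edge-swap chain with 10 x |E|
#' attempted swaps per replicate). For each ensemble the mean and standard
#' deviation of both clustering coefficients and the component count are
#' reported, with the z-score of the observed value. The input network is
#' never mutated.
#'
#' @param net a [GeneNetwork-class] with >= 2 edges.
#' @param n_replicates ensemble size (>= 10).
#' @param seed integer RNG seed.
#' @return A list with `observed`, `uniform` and `rewired` summaries and
#'   `z_scores` (per metric and ensemble).
#' @export
randomBaselines <- function(net, n_replicates = 100, seed = 1L) {
  if (n_replicates < 10) stop("'n_replicates' must be >= 10")
  if (numEdges(net) < 2)
    stop("degree sequence not rewirable with fewer than 2 edges")
  g <- .as_igraph(net)
  nn <- igraph::vcount(g); ne <- igraph::ecount(g)
  measure <- function(h) c(
    cc_mean_local = .mean_local_cc(h),
    cc_transitivity = {
      t <- igraph::transitivity(h, type = "global")
      if (is.nan(t)) 0 else t
    },
    n_components = igraph::components(h)$no)
  obs <- measure(g)
  .with_seed(seed, {
    unif <- t(replicate(n_replicates,
                        measure(igraph::sample_gnm(nn, ne))))
    rew <- t(replicate(n_replicates, {
      h <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                    niter = 10 * ne))
      measure(h)
    }))
    zs <- function(mat) (obs - colMeans(mat)) /
      pmax(apply(mat, 2, stats::sd), .Machine$double.eps)
    list(observed = obs,
         uniform = list(mean = colMeans(unif),
                        sd = apply(unif, 2, stats::sd)),
         rewired = list(mean = colMeans(rew),
                        sd = apply(rew, 2, stats::sd)),
         z_scores = list(uniform = zs(unif), rewired = zs(rew)),
         n_replicates = n_replicates, seed = as.integer(seed))
  })
}
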