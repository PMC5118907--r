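# Independent brute-force oracles used to cross-check the graph and set
# machinery. Everything here works from first principles (adjacency
# matrices, per-element membership loops) and never calls the package's own
# implementations or igraph.

bf_adjacency <- function(nodes, edges) {
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    A[edges$source[r], edges$target[r]] <- 1L
    A[edges$target[r], edges$source[r]] <- 1L
  }
  A
}

bf_components <- function(A) {
  n <- nrow(A)
  comp <- rep(0L, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cid <- cid + 1L
    frontier <- s
    comp[s] <- cid
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        nbr <- which(A[v, ] == 1L & comp == 0L)
        comp[nbr] <- cid
        nxt <- c(nxt, nbr)
      }
      frontier <- nxt
    }
  }
  comp
}

bf_triangles_per_node <- function(A) {
  n <- nrow(A)
  tri <- integer(n)
  for (i in seq_len(n)) {
    nbr <- which(A[i, ] == 1L)
    cnt <- 0L
    if (length(nbr) >= 2) {
      pairs <- utils::combn(nbr, 2)
      for (c2 in seq_len(ncol(pairs)))
        if (A[pairs[1, c2], pairs[2, c2]] == 1L) cnt <- cnt + 1L
    }
    tri[i] <- cnt
  }
  tri
}

bf_metrics <- function(nodes, edges) {
  A <- bf_adjacency(nodes, edges)
  deg <- rowSums(A)
  tri <- bf_triangles_per_node(A)
  comp <- bf_components(A)
  local_cc <- ifelse(deg < 2, 0, tri / (deg * (deg - 1) / 2))
  triples <- sum(deg * (deg - 1) / 2)
  list(
    degree = deg,
    n_components = max(comp),
    component_sizes = sort(as.integer(table(comp)), decreasing = TRUE),
    giant_size = max(table(comp)),
    n_triangles = sum(tri) / 3,
    cc_mean_local = mean(local_cc),
    cc_transitivity = if (triples == 0) 0 else sum(tri) / triples)
}

# uniform random simple graph on <= n_max nodes as an edge data.frame
random_edge_list <- function(n_nodes, n_edges) {
  nodes <- sprintf("v%02d", seq_len(n_nodes))
  all_pairs <- utils::combn(nodes, 2)
  pick <- sample(ncol(all_pairs), min(n_edges, ncol(all_pairs)))
  data.frame(source = all_pairs[1, pick], target = all_pairs[2, pick],
             weight = stats::runif(length(pick)), stringsAsFactors = FALSE)
}

bf_jaccard <- function(a, b) {
  u <- unique(c(a, b))
  inter <- 0L
  for (el in u) if (el %in% a && el %in% b) inter <- inter + 1L
  if (!length(u)) return(1)
  inter / length(u)
}

bf_venn_counts <- function(sets) {
  u <- unique(unlist(sets))
  out <- list()
  for (el in u) {
    members <- names(sets)[vapply(sets, function(s) el %in% s, logical(1))]
    key <- paste(members, collapse = "&")
    out[[key]] <- c(out[[key]], el)
  }
  vapply(out, length, integer(1))
}

bf_core <- function(cases, reference) {
  core <- cases[[1]]
  for (s in cases[-1]) core <- core[core %in% s]
  sort(core[!core %in% reference])
}

# bivariate Gaussian sampler with given correlation
rbvn <- function(n, rho) {
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
}

# small expression fixture: iid Gaussian features
iid_matrix <- function(p, n, prefix = "f") {
  matrix(stats::rnorm(p * n), p, n,
         dimnames = list(sprintf("%s%03d", prefix, seq_len(p)),
                         sprintf("s%03d", seq_len(n))))
}
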