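test_that("network construction dedups edges and rejects self-pairs", {
  net <- buildNetwork(data.frame(feature_a = c("a", "b"),
                                 feature_b = c("b", "c"), mi = c(1, 2)))
  expect_identical(numNodes(net), 2L + 1L)
  expect_identical(numEdges(net), 2L)
  dup <- buildNetwork(data.frame(feature_a = c("a", "b"),
                                 feature_b = c("b", "a"),
                                 mi = c(0.5, 0.7)))
  expect_identical(numEdges(dup), 1L)
  expect_identical(edgeTable(dup)$weight, 0.7)
  expect_identical(edgeTable(dup)$source, "a")       # canonical orientation
  expect_error(buildNetwork(data.frame(feature_a = "x", feature_b = "x",
                                       mi = 1)), "self-pairs")
  empty <- buildNetwork(NULL)
  expect_identical(numNodes(empty), 0L)
  expect_identical(numEdges(empty), 0L)
})

test_that("metrics match hand-computed values on canonical graphs", {
  k3 <- buildNetwork(data.frame(feature_a = c("a", "a", "b"),
                                feature_b = c("b", "c", "c"), mi = 1:3))
  m <- computeMetrics(k3)
  expect_identical(m$n_nodes, 3L)
  expect_identical(m$n_edges, 3L)
  expect_identical(m$n_components, 1L)
  expect_equal(m$clustering_coefficient_mean_local, 1)
  expect_equal(m$clustering_coefficient_transitivity, 1)
  expect_equal(m$node_link_ratio, 1)

  path <- buildNetwork(data.frame(feature_a = c("a", "b"),
                                  feature_b = c("b", "c"), mi = c(1, 1)))
  mp <- computeMetrics(path)
  expect_equal(mp$clustering_coefficient_mean_local, 0)
  expect_equal(mp$clustering_coefficient_transitivity, 0)
  expect_identical(mp$n_components, 1L)

  # K4 minus one edge: local CCs are 1, 1, 2/3, 2/3 -> mean 5/6
  k4m <- buildNetwork(data.frame(
    feature_a = c("a", "a", "a", "b", "b"),
    feature_b = c("b", "c", "d", "c", "d"), mi = rep(1, 5)))
  m4 <- computeMetrics(k4m)
  expect_equal(m4$clustering_coefficient_mean_local, 5 / 6)
  expect_equal(m4$clustering_coefficient_transitivity, 0.75)

  # degree sum identity and component size bookkeeping
  expect_identical(sum(m4$degree), 2L * m4$n_edges)
  expect_identical(sum(m4$component_sizes), m4$n_nodes)
})

test_that("giant component selection follows the stated tie-breaks", {
  three <- buildNetwork(data.frame(
    feature_a = c("a", "a", "b", "c", "x", "y", "p"),
    feature_b = c("b", "c", "c", "d", "y", "z", "q"),
    mi = rep(1, 7)))
  g <- giantComponent(three)                 # sizes 4, 3, 2
  expect_setequal(nodeSet(g), c("a", "b", "c", "d"))
  expect_identical(computeMetrics(g)$n_components, 1L)

  # tie on node count: more edges wins
  tie <- buildNetwork(data.frame(
    feature_a = c("a", "a", "b", "x", "y"),
    feature_b = c("b", "c", "c", "y", "z"), mi = rep(1, 5)))
  expect_setequal(nodeSet(giantComponent(tie)), c("a", "b", "c"))

  # tie on nodes and edges: lexicographically smallest label wins
  tie2 <- buildNetwork(data.frame(feature_a = c("m", "a"),
                                  feature_b = c("n", "b"), mi = c(1, 1)))
  expect_setequal(nodeSet(giantComponent(tie2)), c("a", "b"))

  single <- buildNetwork(data.frame(feature_a = "a", feature_b = "b",
                                    mi = 1))
  expect_identical(edgeKeys(giantComponent(single)), edgeKeys(single))
  expect_error(giantComponent(buildNetwork(NULL)), "empty")
})

test_that("hub ranking and ego networks behave at the boundaries", {
  star <- buildNetwork(data.frame(
    feature_a = rep("hub", 5),
    feature_b = paste0("leaf", 1:5), mi = rep(1, 5)))
  top <- hubRanking(star, 1)
  expect_identical(top$gene, "hub")
  expect_identical(top$degree, 5L)
  all_nodes <- hubRanking(star, 100)
  expect_identical(nrow(all_nodes), 6L)
  # equal degrees -> lexicographic order
  pair <- buildNetwork(data.frame(feature_a = c("z", "a"),
                                  feature_b = c("zz", "b"), mi = c(1, 1)))
  expect_identical(hubRanking(pair, 2)$gene, c("a", "b"))
  expect_error(hubRanking(star, 0), ">= 1")

  tri <- buildNetwork(data.frame(feature_a = c("a", "a", "b"),
                                 feature_b = c("b", "c", "c"), mi = 1:3))
  expect_identical(edgeKeys(egoNetwork(tri, "a")), edgeKeys(tri))
  path <- buildNetwork(data.frame(feature_a = c("a", "b"),
                                  feature_b = c("b", "c"), mi = c(1, 1)))
  ego_a <- egoNetwork(path, "a")
  expect_identical(edgeKeys(ego_a), "a|b")
  expect_identical(numNodes(ego_a), 2L)
  expect_error(egoNetwork(path, "zz"), "zz")
})

test_that("metrics agree with brute force on random small graphs", {
  withr::with_seed(99, {
    for (rep in 1:30) {
      n <- sample(4:12, 1)
      m <- sample(seq_len(n * (n - 1) / 2), 1)
      edges <- random_edge_list(n, m)
      net <- buildNetwork(edges)
      got <- computeMetrics(net)
      want <- bf_metrics(nodeSet(net), edgeTable(net))
      expect_identical(got$n_components, want$n_components)
      expect_identical(got$component_sizes, want$component_sizes)
      expect_equal(got$clustering_coefficient_mean_local,
                   want$cc_mean_local)
      expect_equal(got$clustering_coefficient_transitivity,
                   want$cc_transitivity)
      expect_identical(unname(got$degree[names(want$degree)]),
                       as.integer(unname(want$degree)))
      expect_identical(numNodes(giantComponent(net)),
                       as.integer(want$giant_size))
    }
  })
})

test_that("trees have zero local clustering, complete graphs one", {
  withr::with_seed(5, {
    # random tree on 8 nodes
    nodes <- paste0("t", 1:8)
    parent <- vapply(2:8, function(i) sample(i - 1, 1), integer(1))
    tree <- buildNetwork(data.frame(feature_a = nodes[parent],
                                    feature_b = nodes[2:8],
                                    mi = rep(1, 7)))
    expect_equal(computeMetrics(tree)$clustering_coefficient_mean_local, 0)
    full <- utils::combn(paste0("k", 1:6), 2)
    k6 <- buildNetwork(data.frame(feature_a = full[1, ],
                                  feature_b = full[2, ],
                                  mi = rep(1, ncol(full))))
    expect_equal(computeMetrics(k6)$clustering_coefficient_mean_local, 1)
  })
})
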