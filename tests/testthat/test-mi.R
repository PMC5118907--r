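test_that("kernel MI tracks the bivariate-Gaussian closed form", {
  withr::with_seed(11, {
    for (rho in c(0, 0.5, 0.9)) {
      xy <- rbvn(1000, rho)
      truth <- -0.5 * log(1 - rho^2)
      expect_lt(abs(estimateMI(xy[, 1], xy[, 2]) - truth), 0.05)
    }
  })
})

test_that("MI is symmetric, rank-invariant and handles degenerate input", {
  withr::with_seed(2, {
    xy <- rbvn(300, 0.6)
    x <- xy[, 1]; y <- xy[, 2]
    expect_identical(estimateMI(x, y), estimateMI(y, x))
    # strictly monotone transform leaves the copula estimate unchanged
    expect_identical(estimateMI(x, y), estimateMI(exp(x), y))
    expect_identical(estimateMI(x, y), estimateMI(x, y^3 + 5 * y))
    expect_error(estimateMI(x, y[-1]), "same length")
    expect_error(estimateMI(x[1:5], y[1:5]), "at least 10")
    expect_warning(mi0 <- estimateMI(rep(1, 50), y[1:50]), "constant")
    expect_identical(mi0, 0)
  })
})

test_that("MI ranking is monotone in the planted correlation", {
  withr::with_seed(4, {
    rhos <- seq(0.1, 0.9, by = 0.1)
    mis <- vapply(rhos, function(r) {
      xy <- rbvn(1000, r)
      estimateMI(xy[, 1], xy[, 2])
    }, numeric(1))
    expect_gt(cor(mis, rhos, method = "spearman"), 0.95)
  })
})

test_that("all-pairs MI covers each unordered pair exactly once", {
  withr::with_seed(8, {
    m <- iid_matrix(4, 60)
    ints <- allPairsMI(m)
    expect_identical(nrow(ints), 6L)                       # C(4, 2)
    expect_true(all(ints$feature_a < ints$feature_b))
    expect_false(anyDuplicated(pairKey(ints$feature_a, ints$feature_b)) > 0)
    # permuting the feature rows yields the identical scored set
    perm <- m[c(3, 1, 4, 2), ]
    ints2 <- allPairsMI(perm)
    expect_equal(ints[order(pairKey(ints$feature_a, ints$feature_b)), ],
                 ints2[order(pairKey(ints2$feature_a, ints2$feature_b)), ],
                 ignore_attr = TRUE)
    expect_error(allPairsMI(m[1, , drop = FALSE]), "at least 2")
  })
})

test_that("within-module pairs dominate the MI ranking", {
  d <- syntheticDesign(n_genes = 60, phenotypes = c(A = 100),
                       n_modules = 1, module_size = 6, rho = 0.8,
                       multiprobe_gene_fraction = 0,
                       unmapped_probe_fraction = 0, seed = 31)
  sim <- generateExpression(d)
  ints <- allPairsMI(exprsValues(sim$expression))
  key <- pairKey(sub("_p1", "", ints$feature_a),
                 sub("_p1", "", ints$feature_b))
  planted <- key %in% truthEdgeSet(sim$truth, "A")
  expect_gt(min(ints$mi[planted]),
            quantile(ints$mi[!planted], 0.99))
})

test_that("top-K selection is deterministic with lexicographic ties", {
  df <- data.frame(feature_a = c("a", "a", "a", "b", "c"),
                   feature_b = c("b", "c", "d", "c", "d"),
                   mi = c(0.9, 0.7, 0.5, 0.3, 0.1))
  expect_identical(selectTopK(df, 3)$mi, c(0.9, 0.7, 0.5))
  tie <- data.frame(feature_a = c("z", "a", "m"),
                    feature_b = c("zz", "b", "n"),
                    mi = c(0.5, 0.5, 0.5))
  expect_identical(selectTopK(tie, 2)$feature_a, c("a", "m"))
  expect_warning(all_of_them <- selectTopK(df, 99), "exceeds")
  expect_identical(nrow(all_of_them), 5L)
  expect_error(selectTopK(df, 0), ">= 1")
  # threshold mode agrees with top-K at the implied cutoff
  expect_identical(selectByThreshold(df, 0.5), selectTopK(df, 3))
})

test_that("probe collapse applies the discard and dedup rules", {
  map <- data.frame(probe = c("p1", "p2", "p3", "p4"),
                    symbol = c("GA", "GA", "GB", NA))
  edges <- data.frame(feature_a = c("p1", "p2", "p1", "p3"),
                      feature_b = c("p3", "p3", "p2", "p4"),
                      mi = c(0.5, 0.7, 0.9, 0.8))
  out <- collapseToGenes(edges, map)
  expect_identical(out,
                   data.frame(feature_a = "GA", feature_b = "GB", mi = 0.7))
  # all probes unmapped -> empty
  none <- data.frame(probe = c("p1", "p3"), symbol = c(NA, NA))
  expect_identical(nrow(collapseToGenes(edges[1, ], none)), 0L)
  # identity map -> unchanged set
  idmap <- data.frame(probe = c("x", "y", "z"), symbol = c("x", "y", "z"))
  ed <- data.frame(feature_a = c("x", "y"), feature_b = c("y", "z"),
                   mi = c(0.2, 0.4))
  expect_equal(collapseToGenes(ed, idmap)[order(collapseToGenes(ed, idmap)$feature_a), ],
               ed[order(ed$feature_a), ], ignore_attr = TRUE)
  # minimum p-value is retained alongside maximum MI
  edges$p_value <- c(0.04, 0.01, 0.5, 0.2)
  expect_identical(collapseToGenes(edges, map)$p_value, 0.01)
})

test_that("permutation null yields calibrated p-values and thresholds", {
  withr::with_seed(14, {
    m <- iid_matrix(30, 60)
    null <- buildNull(m, n_permutations = 20, n_pairs_sampled = 100,
                      seed = 3)
    N <- length(null@pooled)
    expect_identical(N, 2000L)
    # p-value of the pooled maximum is the empirical resolution
    expect_equal(pValue(null, max(null@pooled)), 1 / N)
    expect_equal(pValue(null, -1), 1)
    # monotone: smaller p -> larger threshold
    ths <- vapply(c(0.5, 0.05, 1e-3, 1e-6, 1e-10),
                  function(p) miThreshold(null, p), numeric(1))
    expect_true(all(diff(ths) > 0))
    expect_identical(miThreshold(null, 1), 0)
    # extrapolated threshold exceeds every pooled value
    expect_gt(miThreshold(null, 1e-10), max(null@pooled))
    # reproducibility under the seed
    null2 <- buildNull(m, n_permutations = 20, n_pairs_sampled = 100,
                       seed = 3)
    expect_identical(null@pooled, null2@pooled)
    expect_error(buildNull(m, n_permutations = 2, n_pairs_sampled = 10,
                           seed = 1), ">= 100")
  })
})

test_that("empirical threshold sits at the requested quantile", {
  pool <- sort((1:200) / 200)   # survival of pool[k] is (200 - k + 1)/200
  null <- methods::new("MINull", pooled = pool, sample_size = 50L,
                       n_permutations = 2L, n_pairs = 100L,
                       tail_intercept = 0, tail_slope = -30,
                       tail_fraction = 0.05, seed = 1L)
  # smallest pooled MI whose survival <= 0.05: pool[191] = 0.955
  expect_equal(miThreshold(null, 0.05), 0.955)
  expect_equal(pValue(null, 0.955), 0.05)
})

test_that("DPI pruning removes the weakest edge of a triangle", {
  tri <- data.frame(feature_a = c("a", "a", "b", "c"),
                    feature_b = c("b", "c", "c", "d"),
                    mi = c(0.9, 0.8, 0.2, 0.5))
  out <- applyDPI(tri, tolerance = 0)
  expect_setequal(pairKey(out$feature_a, out$feature_b),
                  c("a|b", "a|c", "c|d"))
  # a generous tolerance keeps the triangle intact
  keep <- applyDPI(tri, tolerance = 0.8)
  expect_identical(nrow(keep), 4L)
  expect_error(applyDPI(tri, tolerance = 1), "tolerance")
})
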