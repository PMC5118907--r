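batch_fixture <- function(p = 60, n_per = 50, shift = 2, scale = 1,
                          seed = 21) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(p * 2 * n_per, mean = 8), p, 2 * n_per,
                dimnames = list(sprintf("g%03d", seq_len(p)),
                                sprintf("s%03d", seq_len(2 * n_per))))
    batch <- rep(c("A", "B"), each = n_per)
    v[, batch == "B"] <- (v[, batch == "B"] - 8) * scale + 8 + shift
    list(v = v, batch = batch,
         phenotype = rep(c("x", "y"), n_per))
  })
}

test_that("single-batch adjustment is the identity", {
  f <- batch_fixture(p = 20, n_per = 10, shift = 0)
  out <- combatAdjust(f$v, batch = rep("only", 20), covariates = NULL)
  expect_equal(out$adjusted, f$v, tolerance = 1e-8)
  expect_true(all(out$model$gamma_star == 0))
  expect_true(all(out$model$delta_star_sq == 1))
})

test_that("planted location and scale batch effects are removed", {
  # a shift common to all genes is removed from the pooled signal
  f <- batch_fixture(shift = 2, scale = 1)
  adj <- combatAdjust(f$v, batch = f$batch, covariates = f$phenotype)
  d <- rowMeans(adj$adjusted[, f$batch == "B"]) -
    rowMeans(adj$adjusted[, f$batch == "A"])
  expect_lt(abs(mean(d)), 0.1)
  expect_lt(mean(abs(d)), 0.1 * 2)   # per-gene residual << planted shift

  # gene-specific shifts (the empirical-Bayes regime) are tracked per gene
  withr::with_seed(22, {
    p <- 60; n_per <- 50
    v <- matrix(rnorm(p * 2 * n_per, mean = 8), p, 2 * n_per,
                dimnames = list(sprintf("g%03d", 1:p),
                                sprintf("s%03d", 1:(2 * n_per))))
    batch <- rep(c("A", "B"), each = n_per)
    shifts <- rnorm(p, mean = 2, sd = 1)
    v[, batch == "B"] <- v[, batch == "B"] + shifts
    out <- combatAdjust(v, batch = batch,
                        covariates = rep(c("x", "y"), n_per))$adjusted
    resid <- rowMeans(out[, batch == "B"]) - rowMeans(out[, batch == "A"])
    expect_lt(mean(abs(resid)), 0.1)
    expect_lt(max(abs(resid)), 0.1 * max(abs(shifts)))
  })

  f2 <- batch_fixture(p = 60, n_per = 100, shift = 0, scale = 3)
  adj2 <- combatAdjust(f2$v, batch = f2$batch, covariates = NULL)
  ratio <- apply(adj2$adjusted[, f2$batch == "B"], 1, var) /
    apply(adj2$adjusted[, f2$batch == "A"], 1, var)
  expect_lt(abs(median(ratio) - 1), 0.25)
  expect_gte(mean(abs(ratio - 1) < 0.25), 0.9)
  # raw scale estimates actually saw the planted factor
  expect_gt(median(adj2$model$delta_hat_sq[2, ] /
                   adj2$model$delta_hat_sq[1, ]), 4)
})

test_that("re-adjustment is a strong contraction", {
  # the EB posterior re-shrinks pure sampling noise on a second pass, so
  # exact idempotency is not attainable; the second pass must change the
  # data by a small fraction of what the first pass removed
  f <- batch_fixture(shift = 1.5, scale = 2)
  once <- combatAdjust(f$v, batch = f$batch,
                       covariates = f$phenotype)$adjusted
  twice <- combatAdjust(once, batch = f$batch,
                        covariates = f$phenotype)$adjusted
  first_change <- sqrt(mean((once - f$v)^2))
  second_change <- sqrt(mean((twice - once)^2))
  expect_lt(second_change, 0.05 * first_change)
})

test_that("adjustment matches the reference empirical-Bayes implementation", {
  f <- batch_fixture(p = 40, n_per = 25, shift = 1, scale = 2, seed = 5)
  mine <- combatAdjust(f$v, batch = f$batch,
                       covariates = f$phenotype)$adjusted
  ref <- sva::ComBat(f$v, batch = f$batch,
                     mod = stats::model.matrix(~ f$phenotype))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-6)
})

test_that("degenerate batch inputs are handled", {
  f <- batch_fixture(p = 20, n_per = 10)
  expect_error(
    combatAdjust(f$v, batch = c("A", rep("B", 19)), covariates = NULL),
    ">= 2 samples")
  g <- f$v; g[3, ] <- 5
  expect_warning(
    out <- combatAdjust(g, batch = f$batch, covariates = NULL),
    "constant")
  expect_equal(out$adjusted[3, ], g[3, ])  # passed through
})

test_that("cyclic loess preserves identical columns and removes offsets", {
  withr::with_seed(1, {
    base <- rnorm(400, mean = 10)
    two_same <- cbind(a = base, b = base)
    expect_equal(cyclicLoessNormalize(two_same), two_same,
                 tolerance = 1e-10)
    offset <- cbind(a = base, b = base + 1.5)
    norm <- cyclicLoessNormalize(offset)
    expect_lt(abs(diff(colMeans(norm))), 0.05 * 1.5)

    r <- matrix(rnorm(200 * 8, mean = 9), 200, 8)
    r <- sweep(r, 2, seq(-1, 1, length.out = 8), `+`)
    out <- cyclicLoessNormalize(r)
    spread_in <- diff(range(apply(r, 2, median)))
    spread_out <- diff(range(apply(out, 2, median)))
    expect_lte(spread_out, spread_in)
  })
  expect_error(cyclicLoessNormalize(matrix(1:5, ncol = 1)), ">= 2 samples")
})

test_that("pvca attributes variance to the factor that carries it", {
  withr::with_seed(9, {
    p <- 80; n <- 60
    phen <- rep(c("t", "n"), each = n / 2)
    batch <- rep(c("b1", "b2"), n / 2)
    base <- matrix(rnorm(p * n), p, n,
                   dimnames = list(sprintf("g%02d", 1:p),
                                   sprintf("s%02d", 1:n)))
    # strong phenotype signal, no batch signal
    sig <- matrix(0, p, n); sig[1:20, phen == "t"] <- 3
    rep_phen <- pvca(base + sig,
                     factors = list(batch = batch, phenotype = phen))
    expect_lt(rep_phen$fractions["batch"], 0.05)
    expect_gt(rep_phen$fractions["phenotype"], 0.3)
    expect_equal(sum(rep_phen$fractions), 1, tolerance = 1e-9)
    # strong batch shift, no phenotype signal
    shift <- matrix(0, p, n); shift[, batch == "b2"] <- 3
    rep_batch <- pvca(base + shift,
                      factors = list(batch = batch, phenotype = phen))
    expect_gt(rep_batch$fractions["batch"], 0.5)
    expect_equal(sum(rep_batch$fractions), 1, tolerance = 1e-9)
  })
})

test_that("pvca rejects unusable factors", {
  m <- iid_matrix(10, 6)
  expect_error(pvca(m, factors = list(id = colnames(m))), "confounded")
  expect_error(pvca(m, factors = list(f = rep("a", 6))), ">= 2 levels")
  expect_error(pvca(m, factors = list(f = rep(c("a", "b"), 3)),
                    variance_explained_floor = 0), "floor")
})

test_that("comparability pipeline shrinks the PVCA batch fraction", {
  d <- syntheticDesign(n_genes = 80, phenotypes = c(A = 30, B = 30),
                       n_modules = 3, module_size = 5,
                       batch_shift = c(batch1 = 0, batch2 = 1.5),
                       multiprobe_gene_fraction = 0,
                       unmapped_probe_fraction = 0, seed = 13)
  em <- generateExpression(d)$expression
  before <- pvca(em)$fractions["batch"]
  adj <- combatAdjust(em)$adjusted
  norm <- cyclicLoessNormalize(adj)
  after <- pvca(norm)$fractions["batch"]
  expect_lt(after, before)
})
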