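#' Configure the kernel MI estimator
#'
#' The estimator is a Gaussian-kernel plug-in: MI = (1/n) sum_i log
#' j(x_i, y_i) / (m_x(x_i) m_y(y_i)) with leave-one-out kernel density
#' estimates of the joint (j) and the marginals (m), reported in nats and
#' clamped at zero. With the copula transform on (the default), each
#' feature is first rank-transformed to empirical normal scores
#' qnorm((rank - 1/2)/n), which makes the estimate exactly invariant under
#' strictly monotone maps of either variable and gives every feature the
#' same marginal sample. The joint kernel covariance is
#' h^2 * (sample covariance of the pair), so the kernel follows the
#' correlation ridge; marginal bandwidths are h * sd. The bandwidth factor
#' multiplies the Silverman rate h = n^(-1/6) for two dimensions.
#'
#' @param copula_transform logical; rank-transform features first.
#' @param bandwidth_factor positive multiplier on the Silverman bandwidth.
#' @return A list of class `"MIEstimatorConfig"` (units are fixed to nats).
#' @export
miConfig <- function(copula_transform = TRUE, bandwidth_factor = 1) {
  if (bandwidth_factor <= 0) stop("'bandwidth_factor' must be positive")
  structure(list(copula_transform = isTRUE(copula_transform),
                 bandwidth_factor = bandwidth_factor,
                 bandwidth_rule = "silverman", mi_units = "nats"),
            class = c("MIEstimatorConfig", "list"))
}

.normal_scores <- function(x) {
  n <- length(x)
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
}

.mi_transform <- function(x, config) {
  # raw values go straight to the kernel (its covariance adapts to scale)
  if (config$copula_transform) .normal_scores(x) else as.numeric(x)
}

#' Kernel MI between two sample vectors
#'
#' @param x,y numeric vectors of equal length n >= 10, finite values.
#' @param config an [miConfig()] object.
#' @return MI estimate in nats (nonnegative; 0 with a warning for a
#'   constant input).
#' @examples
#' set.seed(1)
#' x <- rnorm(200); y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(200)
#' estimateMI(x, y)            # close to -0.5 * log(1 - 0.81)
#' @export
estimateMI <- function(x, y, config = miConfig()) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (length(x) < 10) stop("need at least 10 paired samples")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (stats::var(x) < .Machine$double.eps ||
      stats::var(y) < .Machine$double.eps) {
    warning("constant input vector; MI is 0")
    return(0)
  }
  cpp_mi_pair(.mi_transform(x, config), .mi_transform(y, config),
              config$bandwidth_factor)
}

#' All-pairs kernel MI of an expression matrix
#'
#' Computes the MI of every unordered pair of distinct features: exactly
#' N(N-1)/2 scored interactions, each pair once, no self-pairs. The result
#' is independent of the feature input order (pairs are reported with
#' `feature_a < feature_b` under C collation and sorted by descending MI,
#' ties by pair order).
#'
#' @param x an [ExpressionMatrix-class] or numeric matrix
#'   (features x samples) with >= 2 features and >= 10 samples.
#' @param config an [miConfig()] object.
#' @return data.frame with columns `feature_a`, `feature_b`, `mi`.
#' @export
allPairsMI <- function(x, config = miConfig()) {
  dat <- .as_matrix_input(x)
  if (nrow(dat) < 2) stop("need at least 2 features")
  if (ncol(dat) < 10) stop("need at least 10 samples")
  if (is.null(rownames(dat))) rownames(dat) <- paste0("f", seq_len(nrow(dat)))
  constant <- apply(dat, 1, function(r) stats::var(r) < .Machine$double.eps)
  if (any(constant))
    warning(sum(constant), " constant feature(s); their pairs score MI 0")
  tx <- apply(t(dat), 2, function(col)
    if (stats::var(col) < .Machine$double.eps) col
    else .mi_transform(col, config))
  mi <- cpp_mi_all_pairs(tx, config$bandwidth_factor)
  p <- nrow(dat)
  i <- rep(seq_len(p - 1), times = (p - 1):1)
  j <- sequence((p - 1):1, from = 2:p)
  ids <- rownames(dat)
  out <- data.frame(feature_a = .chr_pmin(ids[i], ids[j]),
                    feature_b = .chr_pmax(ids[i], ids[j]),
                    mi = mi, stringsAsFactors = FALSE)
  out <- out[order(-out$mi, out$feature_a, out$feature_b,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a permutation null model for MI
#'
#' For randomly sampled feature pairs, one feature's samples are permuted
#' and the MI recomputed; the pooled values over all sampled pairs and
#' permutations form the empirical null for the given sample size. An
#' exponential tail (log survival linear in MI) is fit on the upper
#' `tail_fraction` of the pool for extrapolation below the empirical
#' resolution. Reproducible under a fixed seed.
#'
#' @param x an [ExpressionMatrix-class] or numeric matrix
#'   (features x samples).
#' @param n_permutations permutations per sampled pair.
#' @param n_pairs_sampled number of feature pairs sampled.
#' @param seed integer RNG seed.
#' @param config an [miConfig()] object.
#' @param tail_fraction upper pool fraction used for the tail fit.
#' @return An [MINull-class] object.
#' @export
buildNull <- function(x, n_permutations = 50, n_pairs_sampled = 200,
                      seed = 1L, config = miConfig(),
                      tail_fraction = 0.05) {
  dat <- .as_matrix_input(x)
  if (nrow(dat) < 2) stop("need at least 2 features")
  if (ncol(dat) < 10) stop("need at least 10 samples")
  pool_size <- n_permutations * n_pairs_sampled
  if (pool_size < 100)
    stop("null pool would hold ", pool_size, " values; need >= 100")
  p <- nrow(dat)
  .with_seed(seed, {
    pool <- numeric(pool_size)
    k <- 0L
    for (s in seq_len(n_pairs_sampled)) {
      ij <- sample.int(p, 2)
      xi <- .mi_transform(dat[ij[1], ], config)
      xj <- .mi_transform(dat[ij[2], ], config)
      for (r in seq_len(n_permutations)) {
        k <- k + 1L
        pool[k] <- cpp_mi_pair(xi, sample(xj), config$bandwidth_factor)
      }
    }
    pool <- sort(pool)
    N <- length(pool)
    # exponential tail: log survival vs MI on the upper tail (positive MI)
    tail_idx <- which(seq_len(N) > (1 - tail_fraction) * N & pool > 0)
    surv <- (N - tail_idx + 1) / N
    fit <- stats::lm(log(surv) ~ pool[tail_idx])
    methods::new("MINull", pooled = pool,
                 sample_size = ncol(dat),
                 n_permutations = as.integer(n_permutations),
                 n_pairs = as.integer(n_pairs_sampled),
                 tail_intercept = unname(stats::coef(fit)[1]),
                 tail_slope = unname(stats::coef(fit)[2]),
                 tail_fraction = tail_fraction,
                 seed = as.integer(seed))
  })
}

#' @rdname pValue
#' @export
setMethod("pValue", "MINull", function(null, mi) {
  pool <- null@pooled
  N <- length(pool)
  vapply(mi, function(v) {
    if (v <= pool[N]) {
      # empirical survival: fraction of pooled null values >= v
      max(1L, N - findInterval(v, pool, left.open = TRUE)) / N
    } else {
      min(1 / N, exp(null@tail_intercept + null@tail_slope * v))
    }
  }, numeric(1))
})

#' @rdname miThreshold
#' @export
setMethod("miThreshold", "MINull", function(null, p) {
  if (p <= 0 || p > 1) stop("'p' must lie in (0, 1]")
  if (p >= 1) return(0)
  pool <- null@pooled
  N <- length(pool)
  if (p >= 1 / N) {
    k <- N - floor(p * N) + 1L    # smallest pooled MI with survival <= p
    pool[min(k, N)]
  } else {
    (log(p) - null@tail_intercept) / null@tail_slope
  }
})

#' Keep the top-K interactions by MI
#'
#' @param interactions data.frame from [allPairsMI()] (columns `feature_a`,
#'   `feature_b`, `mi`, optionally `p_value`).
#' @param k number of interactions to keep (>= 1). Ties at the cutoff are
#'   broken by lexicographic pair order; if `k` exceeds the available
#'   pairs, all are returned with a warning.
#' @return The k highest-MI interactions, deterministic ordering.
#' @export
selectTopK <- function(interactions, k) {
  if (k < 1) stop("'k' must be >= 1")
  o <- order(-interactions$mi, interactions$feature_a,
             interactions$feature_b, method = "radix")
  if (k > nrow(interactions)) {
    warning("k = ", k, " exceeds the ", nrow(interactions),
            " available pairs; returning all")
    k <- nrow(interactions)
  }
  out <- interactions[o[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select interactions above an MI threshold
#'
#' Threshold-mode counterpart of [selectTopK()]: keeps interactions with
#' MI >= `mi0`, e.g. `mi0 = miThreshold(null, 1e-10)`.
#'
#' @param interactions data.frame from [allPairsMI()].
#' @param mi0 MI threshold in nats.
#' @return The surviving interactions, sorted by descending MI.
#' @export
selectByThreshold <- function(interactions, mi0) {
  o <- order(-interactions$mi, interactions$feature_a,
             interactions$feature_b, method = "radix")
  out <- interactions[o, , drop = FALSE]
  out <- out[out$mi >= mi0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse probe-level interactions to gene symbols
#'
#' Applies the probe-to-symbol mapping rules: interactions touching an
#' unmapped probe are discarded; pairs whose probes map to the same symbol
#' are discarded (would be self-loops); among duplicate gene pairs the
#' maximum MI (and minimum p-value, when present) is retained.
#'
#' @param interactions data.frame with `feature_a`, `feature_b`, `mi` and
#'   optionally `p_value`.
#' @param map data.frame with columns `probe` and `symbol` (NA or empty
#'   symbol = unmapped), or a named character vector probe -> symbol.
#' @return data.frame of gene-level interactions sorted by descending MI.
#' @export
collapseToGenes <- function(interactions, map) {
  if (is.data.frame(map)) {
    sym <- stats::setNames(as.character(map$symbol), map$probe)
  } else sym <- map
  sym[!is.na(sym) & sym == ""] <- NA_character_
  ga <- unname(sym[interactions$feature_a])
  gb <- unname(sym[interactions$feature_b])
  keep <- !is.na(ga) & !is.na(gb) & ga != gb
  out <- interactions[keep, , drop = FALSE]
  if (!nrow(out)) {
    res <- data.frame(feature_a = character(), feature_b = character(),
                      mi = numeric(), stringsAsFactors = FALSE)
    if ("p_value" %in% colnames(interactions)) res$p_value <- numeric()
    return(res)
  }
  a <- .chr_pmin(ga[keep], gb[keep])
  b <- .chr_pmax(ga[keep], gb[keep])
  key <- paste(a, b, sep = "|")
  o <- order(-out$mi, method = "radix")
  first <- o[!duplicated(key[o])]            # max MI per gene pair
  res <- data.frame(feature_a = a[first], feature_b = b[first],
                    mi = out$mi[first], stringsAsFactors = FALSE)
  if ("p_value" %in% colnames(out))
    res$p_value <- as.numeric(tapply(out$p_value, key, min)[key[first]])
  res <- res[order(-res$mi, res$feature_a, res$feature_b,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Data-processing-inequality pruning
#'
#' Optional ARACNE-style post-filter: for every triangle, the weakest edge
#' is marked for removal when its MI is below the smaller of the other two
#' edges scaled by (1 - `tolerance`); all marks are computed on the
#' original values and applied simultaneously. Off by default in the
#' pipeline: the construction recipe keeps top-ranked interactions.
#'
#' @param interactions data.frame with `feature_a`, `feature_b`, `mi`.
#' @param tolerance fraction in [0, 1); larger values prune less.
#' @return The surviving interactions.
#' @export
applyDPI <- function(interactions, tolerance = 0) {
  if (tolerance < 0 || tolerance >= 1) stop("'tolerance' must be in [0, 1)")
  if (nrow(interactions) < 3) return(interactions)
  mi_of <- stats::setNames(
    interactions$mi, paste(interactions$feature_a, interactions$feature_b,
                           sep = "|"))
  nbr <- split(c(interactions$feature_b, interactions$feature_a),
               c(interactions$feature_a, interactions$feature_b))
  drop <- logical(nrow(interactions))
  for (e in seq_len(nrow(interactions))) {
    a <- interactions$feature_a[e]; b <- interactions$feature_b[e]
    w <- interactions$mi[e]
    common <- intersect(nbr[[a]], nbr[[b]])
    for (k in common) {
      w1 <- mi_of[[pairKey(a, k)]]
      w2 <- mi_of[[pairKey(b, k)]]
      if (w < min(w1, w2) * (1 - tolerance)) { drop[e] <- TRUE; break }
    }
  }
  out <- interactions[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
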