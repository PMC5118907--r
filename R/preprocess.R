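#' Empirical-Bayes location/scale batch adjustment
#'
#' Removes additive (location) and multiplicative (scale) batch artifacts
#' from an expression matrix with the parametric empirical-Bayes model:
#' gene-wise standardization preserving covariate (phenotype) effects,
#' per-batch location (gamma) and scale (delta^2) estimates shrunk toward a
#' normal / inverse-gamma prior whose hyperparameters are estimated by
#' method of moments, then removal of the shrunk effects and return to the
#' original expression scale. Deterministic.
#'
#' A single-batch input is returned unchanged (identity transform). Genes
#' that are constant across all samples cannot be standardized and are
#' passed through unadjusted with a warning.
#'
#' @param x an [ExpressionMatrix-class] or plain numeric matrix
#'   (features x samples).
#' @param batch batch label per sample; defaults to `batchLabels(x)` for an
#'   ExpressionMatrix.
#' @param covariates optional factor to preserve (e.g. phenotype); defaults
#'   to `phenotypeLabels(x)` for an ExpressionMatrix. Use `NULL` for none.
#' @param conv convergence tolerance of the EB iteration.
#' @return A list with `adjusted` (same container as the input) and `model`,
#'   a `"BatchAdjustmentModel"` list holding per-batch raw (`gamma_hat`,
#'   `delta_hat_sq`) and shrunk (`gamma_star`, `delta_star_sq`) location and
#'   scale estimates plus the prior hyperparameters (`gamma_bar`, `tau_sq`,
#'   `a_prior`, `b_prior`).
#' @references The parametric location/scale empirical-Bayes adjustment is
#'   the standard published formulation for microarray batch correction.
#' @export
combatAdjust <- function(x, batch = NULL, covariates = NULL,
                         conv = 1e-4) {
  is_em <- methods::is(x, "ExpressionMatrix")
  if (is_em) {
    if (is.null(batch)) batch <- batchLabels(x)
    if (missing(covariates)) covariates <- phenotypeLabels(x)
  }
  dat <- .as_matrix_input(x)
  if (is.null(batch)) stop("'batch' is required for a plain matrix")
  batch <- as.factor(batch)
  if (length(batch) != ncol(dat)) stop("one batch label per sample required")
  nb <- nlevels(batch)
  n <- ncol(dat)

  model <- list(batches = levels(batch))
  class(model) <- c("BatchAdjustmentModel", "list")
  if (nb == 1L) {
    g <- matrix(0, 1, nrow(dat)); d <- matrix(1, 1, nrow(dat))
    model$gamma_hat <- model$gamma_star <- g
    model$delta_hat_sq <- model$delta_star_sq <- d
    return(list(adjusted = x, model = model))
  }
  sizes <- table(batch)
  if (any(sizes < 2))
    stop("every batch needs >= 2 samples (scale inestimable): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))

  constant <- apply(dat, 1, function(r) stats::var(r) < .Machine$double.eps)
  if (any(constant))
    warning(sum(constant), " constant gene(s) passed through unadjusted")
  work <- dat[!constant, , drop = FALSE]

  B <- stats::model.matrix(~ 0 + batch)
  design <- B
  if (!is.null(covariates)) {
    covariates <- as.factor(covariates)
    if (nlevels(covariates) > 1) {
      C <- stats::model.matrix(~covariates)[, -1, drop = FALSE]
      design <- cbind(B, C)
    }
  }
  # gene-wise least squares; batch-size-weighted grand mean
  beta <- solve(crossprod(design), t(design) %*% t(work))
  grand <- matrix(sizes / n, nrow = 1) %*% beta[seq_len(nb), , drop = FALSE]
  var_pooled <- rowMeans((work - t(design %*% beta))^2)
  stand_mean <- matrix(grand, nrow(work), n)
  if (ncol(design) > nb) {
    tmp <- design; tmp[, seq_len(nb)] <- 0
    stand_mean <- stand_mean + t(tmp %*% beta)
  }
  Z <- (work - stand_mean) / sqrt(var_pooled)

  gamma_hat <- t(sapply(levels(batch), function(b)
    rowMeans(Z[, batch == b, drop = FALSE])))
  delta_hat <- t(sapply(levels(batch), function(b)
    apply(Z[, batch == b, drop = FALSE], 1, stats::var)))
  delta_hat[delta_hat < 1e-8] <- 1e-8

  gamma_bar <- rowMeans(gamma_hat)
  tau_sq <- apply(gamma_hat, 1, stats::var)
  tau_sq <- pmax(tau_sq, 1e-8)
  m <- rowMeans(delta_hat)
  s2 <- pmax(apply(delta_hat, 1, stats::var), 1e-8)
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (bi in seq_len(nb)) {
    sel <- batch == levels(batch)[bi]
    nbat <- sum(sel)
    g_old <- gamma_hat[bi, ]; d_old <- delta_hat[bi, ]
    repeat {
      g_new <- (tau_sq[bi] * nbat * gamma_hat[bi, ] + d_old * gamma_bar[bi]) /
        (tau_sq[bi] * nbat + d_old)
      sum2 <- rowSums((Z[, sel, drop = FALSE] - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[bi]) / (nbat / 2 + a_prior[bi] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
      if (change < conv) break
    }
    gamma_star[bi, ] <- g_old
    delta_star[bi, ] <- d_old
    Z[, sel] <- (Z[, sel, drop = FALSE] - g_old) / sqrt(d_old)
  }
  adj <- Z * sqrt(var_pooled) + stand_mean

  out <- dat
  out[!constant, ] <- adj
  model$gamma_hat <- gamma_hat
  model$delta_hat_sq <- delta_hat
  model$gamma_star <- gamma_star
  model$delta_star_sq <- delta_star
  model$gamma_bar <- gamma_bar
  model$tau_sq <- tau_sq
  model$a_prior <- a_prior
  model$b_prior <- b_prior

  if (is_em) {
    res <- x
    SummarizedExperiment::assay(res, "exprs") <- out
    list(adjusted = res, model = model)
  } else {
    list(adjusted = out, model = model)
  }
}

#' Cyclic loess renormalization
#'
#' Brings all samples to a common dynamic range: for each sample pair a
#' degree-1 loess curve is fit to the difference-versus-average (M vs A)
#' plot of the two columns, half the fitted difference is subtracted from
#' one column and added to the other, and the accumulated corrections are
#' averaged over all pairs. The pass is repeated until `max_iter` passes or
#' the largest column-median drift of a pass falls below `tol`.
#' Deterministic. The pairwise pass is delegated to
#' [limma::normalizeCyclicLoess()] (method "pairs").
#'
#' @param x an [ExpressionMatrix-class] or numeric matrix
#'   (features x samples), >= 2 samples, finite values.
#' @param span loess span (fraction of points).
#' @param max_iter maximum number of full cyclic passes.
#' @param tol column-median drift threshold that stops iteration early.
#' @return Normalized data in the same container as the input.
#' @export
cyclicLoessNormalize <- function(x, span = 0.7, max_iter = 3, tol = 1e-3) {
  dat <- .as_matrix_input(x)
  if (ncol(dat) < 2) stop("cyclic loess needs >= 2 samples")
  if (any(!is.finite(dat))) stop("all values must be finite")
  cur <- dat
  for (it in seq_len(max_iter)) {
    nxt <- limma::normalizeCyclicLoess(cur, span = span, iterations = 1,
                                       method = "pairs")
    drift <- max(abs(apply(nxt, 2, stats::median) -
                     apply(cur, 2, stats::median)))
    cur <- nxt
    if (drift < tol) break
  }
  dimnames(cur) <- dimnames(dat)
  if (methods::is(x, "ExpressionMatrix")) {
    SummarizedExperiment::assay(x, "exprs") <- cur
    x
  } else cur
}

#' Principal variance component analysis
#'
#' Attributes overall expression variance to experimental factors (e.g.
#' batch, phenotype). Principal components of the sample-sample covariance
#' of the gene-centered matrix are retained until their cumulative variance
#' reaches `variance_explained_floor`; each retained component's score
#' variance is decomposed across the factors by method-of-moments one-way
#' ANOVA (negative components truncated at zero) with the remainder
#' assigned to the residual; per-factor fractions are averaged with
#' eigenvalue weights and renormalized to sum to one. Deterministic.
#'
#' @param x an [ExpressionMatrix-class] or numeric matrix
#'   (features x samples).
#' @param factors named list of label vectors (one label per sample), each
#'   with >= 2 levels; for an ExpressionMatrix defaults to its batch and
#'   phenotype labels.
#' @param variance_explained_floor cumulative variance fraction in (0, 1]
#'   deciding how many components are kept.
#' @return A `"PVCAReport"` list: `fractions` (named, includes `residual`,
#'   sums to 1), `n_components`, `eigenvalue_weights`, and the per-component
#'   decomposition `per_component`.
#' @export
pvca <- function(x, factors = NULL, variance_explained_floor = 0.6) {
  dat <- .as_matrix_input(x)
  if (methods::is(x, "ExpressionMatrix") && is.null(factors))
    factors <- list(batch = batchLabels(x), phenotype = phenotypeLabels(x))
  if (is.null(factors) || is.null(names(factors)))
    stop("'factors' must be a named list of label vectors")
  if (variance_explained_floor <= 0 || variance_explained_floor > 1)
    stop("'variance_explained_floor' must lie in (0, 1]")
  n <- ncol(dat)
  for (f in names(factors)) {
    fac <- as.factor(factors[[f]])
    if (length(fac) != n) stop("factor '", f, "' must label every sample")
    if (nlevels(fac) < 2) stop("factor '", f, "' needs >= 2 levels")
    if (nlevels(fac) == n)
      stop("factor '", f, "' is confounded 1:1 with sample id")
    factors[[f]] <- fac
  }
  centered <- dat - rowMeans(dat)
  cv <- crossprod(centered) / (nrow(dat) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  keep <- which(cumsum(ev) / sum(ev) >= variance_explained_floor)[1]
  keep <- max(keep, 1L)
  scores <- eig$vectors[, seq_len(keep), drop = FALSE]

  decomp <- function(s) {
    total <- stats::var(s) * (n - 1) / n
    comps <- vapply(factors, function(fac) {
      k <- nlevels(fac)
      ni <- tabulate(fac)
      gm <- mean(s)
      mi <- tapply(s, fac, mean)
      ssb <- sum(ni * (mi - gm)^2)
      ssw <- sum((s - mi[fac])^2)
      msb <- ssb / (k - 1)
      msw <- ssw / (n - k)
      n0 <- (n - sum(ni^2) / n) / (k - 1)
      max(0, (msb - msw) / n0)
    }, numeric(1))
    resid <- max(total - sum(comps), 1e-12)
    c(comps, residual = resid)
  }
  per_comp <- t(apply(scores, 2, function(s) {
    v <- decomp(s); v / sum(v)
  }))
  w <- ev[seq_len(keep)] / sum(ev[seq_len(keep)])
  fractions <- colSums(per_comp * w)
  fractions <- fractions / sum(fractions)
  out <- list(fractions = fractions, n_components = keep,
              eigenvalue_weights = w, per_component = per_comp)
  class(out) <- c("PVCAReport", "list")
  out
}

#' @export
print.PVCAReport <- function(x, ...) {
  cat("PVCA variance fractions (", x$n_components, " components):\n",
      sep = "")
  print(round(x$fractions, 4))
  invisible(x)
}
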