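#' Specify a synthetic expression study design
#'
#' Describes a multi-phenotype expression cohort with planted, phenotype-
#' specific co-expression modules, batch artifacts and a probe layer. The
#' defaults describe the package's reference validation cohort: 300 genes,
#' three phenotypes of 150 samples each, per phenotype twelve disjoint
#' modules of ten genes with within-module correlation 0.8, two balanced
#' batches with no artifact, and a probe layer in which every gene has one
#' primary probe, 10% of genes carry 1-2 extra replicate probes and 5%
#' extra probes map to no gene symbol.
#'
#' Within one phenotype, genes of a module are equicorrelated (compound
#' symmetry): pairwise correlation is exactly `rho` irrespective of
#' `noise_sd`, which sets the expression-unit scale of the stochastic part.
#' Modules of different phenotypes may overlap in genes; modules within one
#' phenotype must be disjoint.
#'
#' @param n_genes number of genes.
#' @param phenotypes named integer vector: samples per phenotype label.
#' @param modules optional list, one element per phenotype (named as
#'   `phenotypes`), each a list of module specs `list(genes =, rho =)`.
#'   When `NULL`, `n_modules` modules of `module_size` consecutive genes are
#'   planted per phenotype, staggered by `module_stagger` genes between
#'   successive phenotypes so phenotypes share part of their architecture.
#' @param n_modules,module_size,rho default module layout parameters.
#' @param module_stagger gene offset between successive phenotypes' module
#'   blocks (controls cross-phenotype overlap of planted structure).
#' @param batch_shift named numeric: additive per-batch location offset
#'   (expression units), applied to every gene of the batch.
#' @param batch_scale named numeric (> 0): per-batch multiplicative factor
#'   on the noise scale.
#' @param noise_sd standard deviation of the stochastic component
#'   (expression units, > 0).
#' @param baseline_mean,baseline_sd per-gene baseline log2 intensity
#'   distribution.
#' @param probe_noise_sd independent measurement noise added to each
#'   replicate (non-primary) probe.
#' @param multiprobe_gene_fraction fraction of genes in [0, 1) carrying 2-3
#'   probes.
#' @param unmapped_probe_fraction fraction in [0, 1): extra pure-noise
#'   probes with no gene symbol, as a fraction of the gene count.
#' @param seed integer RNG seed; fixing it fixes every generated artifact.
#' @return A validated list of class `"SyntheticDesign"`.
#' @seealso [generateExpression()], [truthEdgeSet()]
#' @export
syntheticDesign <- function(n_genes = 300,
                            phenotypes = c(LuminalA = 150, LuminalB = 150,
                                           NonTumor = 150),
                            modules = NULL,
                            n_modules = 12, module_size = 10, rho = 0.8,
                            module_stagger = 40,
                            batch_shift = c(batch1 = 0, batch2 = 0),
                            batch_scale = c(batch1 = 1, batch2 = 1),
                            noise_sd = 1,
                            baseline_mean = 8, baseline_sd = 1.5,
                            probe_noise_sd = 0.25,
                            multiprobe_gene_fraction = 0.1,
                            unmapped_probe_fraction = 0.05,
                            seed = 1001L) {
  if (n_genes < 1) stop("'n_genes' must be positive")
  if (is.null(names(phenotypes)) || anyDuplicated(names(phenotypes)))
    stop("'phenotypes' must be a named vector with unique labels")
  if (any(phenotypes < 1)) stop("sample counts must be positive")
  genes <- sprintf("g%03d", seq_len(n_genes))
  if (is.null(modules)) {
    modules <- lapply(seq_along(phenotypes) - 1L, function(i) {
      start <- (i * module_stagger) %% n_genes
      lapply(seq_len(n_modules), function(m) {
        idx <- ((start + (m - 1L) * module_size) %% n_genes) +
          seq_len(module_size)
        idx <- ((idx - 1L) %% n_genes) + 1L
        list(genes = genes[idx], rho = rho)
      })
    })
    names(modules) <- names(phenotypes)
  }
  if (!setequal(names(modules), names(phenotypes)))
    stop("'modules' must be named after the phenotypes")
  for (ph in names(modules)) {
    gs <- unlist(lapply(modules[[ph]], `[[`, "genes"))
    if (anyDuplicated(gs))
      stop("module gene sets within phenotype '", ph, "' must be disjoint")
    if (!all(gs %in% genes))
      stop("module genes outside the gene universe in phenotype '", ph, "'")
    rr <- vapply(modules[[ph]], `[[`, numeric(1), "rho")
    if (any(rr < 0 | rr >= 1))
      stop("module 'rho' must lie in [0, 1)")
  }
  if (noise_sd <= 0) stop("'noise_sd' must be > 0")
  if (any(batch_scale <= 0)) stop("'batch_scale' must be > 0")
  if (!setequal(names(batch_shift), names(batch_scale)))
    stop("'batch_shift' and 'batch_scale' must name the same batches")
  if (multiprobe_gene_fraction < 0 || multiprobe_gene_fraction >= 1 ||
      unmapped_probe_fraction < 0 || unmapped_probe_fraction >= 1)
    stop("probe-layer fractions must lie in [0, 1)")
  n_extra <- round(unmapped_probe_fraction * n_genes)
  n_multi <- round(multiprobe_gene_fraction * n_genes)
  design <- list(
    n_genes = as.integer(n_genes), genes = genes,
    n_probes = as.integer(n_genes + n_multi + n_extra), # lower bound; 2-3
    phenotypes = phenotypes, modules = modules,
    batch_shift = batch_shift, batch_scale = batch_scale,
    noise_sd = noise_sd, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, probe_noise_sd = probe_noise_sd,
    multiprobe_gene_fraction = multiprobe_gene_fraction,
    unmapped_probe_fraction = unmapped_probe_fraction,
    seed = as.integer(seed))
  class(design) <- "SyntheticDesign"
  design
}

#' Generate a synthetic expression cohort
#'
#' Draws the cohort described by a [syntheticDesign()]: per phenotype, genes
#' of one module are samples of an equicorrelated multivariate Gaussian with
#' pairwise correlation `rho`; genes in no module are independent. Batch
#' location shifts and noise-scale factors are applied after the correlation
#' structure. The probe layer then expands genes into probes: every gene has
#' a primary probe carrying its exact signal; selected genes get 1-2 extra
#' replicate probes (signal plus independent probe noise); a pool of extra
#' probes maps to no symbol. Deterministic for a fixed design seed.
#'
#' @param design a `"SyntheticDesign"` object.
#' @return A list with elements
#'   \describe{
#'     \item{expression}{[ExpressionMatrix-class], probes x samples.}
#'     \item{truth}{`"GroundTruth"` list: `planted_edges` (canonical
#'       `"a|b"` keys per phenotype), `module_membership` (gene -> module id
#'       per phenotype), `batch_params` (realized shift/scale per batch).}
#'     \item{map}{data.frame `probe`, `symbol` (NA symbol = unmapped).}
#'   }
#' @examples
#' d <- syntheticDesign(n_genes = 20, phenotypes = c(A = 30), n_modules = 2,
#'                      module_size = 4, seed = 7)
#' sim <- generateExpression(d)
#' dim(exprsValues(sim$expression))
#' @export
generateExpression <- function(design) {
  stopifnot(inherits(design, "SyntheticDesign"))
  .with_seed(design$seed, {
    genes <- design$genes
    n_genes <- design$n_genes
    batches <- names(design$batch_shift)
    baseline <- stats::rnorm(n_genes, design$baseline_mean,
                             design$baseline_sd)
    names(baseline) <- genes

    # latent gene signals per phenotype (correlation structure first)
    sample_ids <- character(); phen <- character(); batch <- character()
    latent <- NULL
    for (ph in names(design$phenotypes)) {
      ns <- design$phenotypes[[ph]]
      G <- matrix(stats::rnorm(n_genes * ns), n_genes, ns)
      for (mod in design$modules[[ph]]) {
        r <- mod$rho
        z <- stats::rnorm(ns)
        idx <- match(mod$genes, genes)
        G[idx, ] <- sqrt(r) * matrix(z, length(idx), ns, byrow = TRUE) +
          sqrt(1 - r) * G[idx, ]
      }
      ids <- sprintf("%s_s%03d", ph, seq_len(ns))
      b <- rep_len(batches, ns)        # balanced, interleaved batches
      sample_ids <- c(sample_ids, ids)
      phen <- c(phen, rep(ph, ns))
      batch <- c(batch, b)
      latent <- cbind(latent, G)
    }
    colnames(latent) <- sample_ids
    rownames(latent) <- genes

    # batch artifacts applied after the correlation structure
    shift <- design$batch_shift[batch]
    scale <- design$batch_scale[batch]
    expr_gene <- baseline +
      sweep(sweep(latent, 2, scale * design$noise_sd, `*`), 2, shift, `+`)

    # probe layer
    n_multi <- round(design$multiprobe_gene_fraction * n_genes)
    multi_genes <- if (n_multi)
      sort(sample.int(n_genes, n_multi)) else integer()
    probe_rows <- list(); probe_ids <- character(); probe_sym <- character()
    for (g in seq_len(n_genes)) {
      probe_rows[[length(probe_rows) + 1L]] <- expr_gene[g, ]
      probe_ids <- c(probe_ids, paste0(genes[g], "_p1"))
      probe_sym <- c(probe_sym, genes[g])
      if (g %in% multi_genes) {
        extra <- sample(1:2, 1)
        for (k in seq_len(extra)) {
          probe_rows[[length(probe_rows) + 1L]] <- expr_gene[g, ] +
            stats::rnorm(length(sample_ids), 0, design$probe_noise_sd)
          probe_ids <- c(probe_ids, paste0(genes[g], "_p", k + 1L))
          probe_sym <- c(probe_sym, genes[g])
        }
      }
    }
    n_unmapped <- round(design$unmapped_probe_fraction * n_genes)
    for (k in seq_len(n_unmapped)) {
      probe_rows[[length(probe_rows) + 1L]] <-
        design$baseline_mean + stats::rnorm(length(sample_ids))
      probe_ids <- c(probe_ids, sprintf("unk_p%03d", k))
      probe_sym <- c(probe_sym, NA_character_)
    }
    values <- do.call(rbind, probe_rows)
    dimnames(values) <- list(probe_ids, sample_ids)

    truth <- list(
      planted_edges = lapply(design$modules, function(mods) {
        keys <- unlist(lapply(mods, function(m) {
          p <- utils::combn(.chr_sort(m$genes), 2)
          pairKey(p[1, ], p[2, ])
        }))
        .chr_sort(unique(keys))
      }),
      module_membership = lapply(design$modules, function(mods) {
        mm <- unlist(lapply(seq_along(mods), function(i)
          stats::setNames(rep(i, length(mods[[i]]$genes)), mods[[i]]$genes)))
        mm
      }),
      batch_params = list(shift = design$batch_shift,
                          scale = design$batch_scale))
    class(truth) <- "GroundTruth"

    list(expression = ExpressionMatrix(values, phenotype = phen,
                                       batch = batch),
         truth = truth,
         map = data.frame(probe = probe_ids, symbol = probe_sym,
                          stringsAsFactors = FALSE))
  })
}

#' Planted edge set for one phenotype
#'
#' All unordered within-module gene pairs planted for a phenotype, as
#' canonical `"a|b"` keys (see [pairKey()]). A module of m genes
#' contributes m(m-1)/2 pairs; modules never contribute cross-module pairs.
#'
#' @param truth the `"GroundTruth"` element of [generateExpression()].
#' @param phenotype phenotype label.
#' @return Character vector of canonical pair keys.
#' @export
truthEdgeSet <- function(truth, phenotype) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (!phenotype %in% names(truth$planted_edges))
    stop("unknown phenotype: '", phenotype, "'")
  truth$planted_edges[[phenotype]]
}
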