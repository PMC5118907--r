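#' End-to-end inference pipeline
#'
#' Runs the full workflow on one cohort: optional comparability
#' preprocessing (per-group empirical-Bayes batch adjustment, then joint
#' cyclic loess renormalization), then per phenotype: all-pairs MI on that
#' phenotype's samples only, top-K selection, probe-to-gene collapse and
#' network construction with topology metrics, permutation-null calibration
#' of the cutoff (the MI of the K-th edge, its null p-value, and the MI
#' threshold at `p_report`), followed by cross-phenotype comparison
#' (Jaccard matrices, Venn partition, optional core set) and an optional
#' cutoff-stability scan per phenotype. Phenotypes with fewer than 10
#' samples are skipped with a warning (MI unreliable). Every stochastic
#' stage receives a seed derived deterministically from `seed`; a rerun
#' with the same inputs is identical.
#'
#' @param expression an [ExpressionMatrix-class].
#' @param map optional probe-to-gene map (data.frame `probe`, `symbol`).
#' @param top_k interactions kept per phenotype network.
#' @param config an [miConfig()] object.
#' @param preprocess logical; run batch adjustment + cyclic loess first.
#'   Adjustment is applied within each phenotype group separately (cases
#'   and controls each see their own batch structure), then all samples are
#'   renormalized together.
#' @param dpi_tolerance `NULL` (no DPI pruning, the default construction)
#'   or a tolerance in [0, 1) for [applyDPI()].
#' @param null_permutations,null_pairs permutation-null pool shape.
#' @param p_report significance level reported as an MI threshold
#'   (default 1e-10, the highest-significance operating point).
#' @param reference_phenotype optional label whose network is the
#'   non-case reference for the core set.
#' @param scan_grid optional cutoff grid for a stability scan per
#'   phenotype (`NULL` skips the scan stage).
#' @param seed global integer seed.
#' @param out_dir optional directory; when given, edge lists, metrics,
#'   comparison tables and the manifest are written there and checksummed.
#' @return A list with `networks`, `metrics`, `interactions` (per
#'   phenotype), `null_models`, `comparison`, `scans` and `manifest`.
#' @export
runPipeline <- function(expression, map = NULL, top_k = 1000,
                        config = miConfig(), preprocess = FALSE,
                        dpi_tolerance = NULL,
                        null_permutations = 50, null_pairs = 200,
                        p_report = 1e-10,
                        reference_phenotype = NULL,
                        scan_grid = NULL, seed = 1L,
                        out_dir = NULL) {
  stopifnot(methods::is(expression, "ExpressionMatrix"))
  seed <- as.integer(seed)
  warnings_log <- character()
  params <- list(top_k = top_k, preprocess = preprocess,
                 dpi_tolerance = dpi_tolerance,
                 null_permutations = null_permutations,
                 null_pairs = null_pairs, p_report = p_report,
                 copula_transform = config$copula_transform,
                 bandwidth_factor = config$bandwidth_factor,
                 reference_phenotype = reference_phenotype,
                 scan_grid = scan_grid, seed = seed)

  if (preprocess) {
    phen <- phenotypeLabels(expression)
    v <- exprsValues(expression)
    for (ph in unique(phen)) {
      sel <- phen == ph
      adj <- combatAdjust(v[, sel, drop = FALSE],
                          batch = batchLabels(expression)[sel],
                          covariates = NULL)
      v[, sel] <- adj$adjusted
    }
    v <- cyclicLoessNormalize(v)
    SummarizedExperiment::assay(expression, "exprs") <- v
  }

  phen <- phenotypeLabels(expression)
  labels <- unique(phen)
  networks <- list(); interactions <- list(); metrics <- list()
  nulls <- list(); scans <- list(); cutoff_stats <- list()
  for (i in seq_along(labels)) {
    ph <- labels[i]
    sel <- phen == ph
    if (sum(sel) < 10) {
      msg <- paste0("phenotype '", ph, "' has ", sum(sel),
                    " samples (< 10); stage skipped, MI unreliable")
      warning(msg)
      warnings_log <- c(warnings_log, msg)
      next
    }
    sub <- exprsValues(expression)[, sel, drop = FALSE]
    ints <- allPairsMI(sub, config)
    null <- buildNull(sub, n_permutations = null_permutations,
                      n_pairs_sampled = null_pairs,
                      seed = seed + 1000L * i, config = config)
    k_use <- min(top_k, nrow(ints))
    sel_ints <- selectTopK(ints, k_use)
    sel_ints$p_value <- pValue(null, sel_ints$mi)
    if (!is.null(dpi_tolerance)) sel_ints <- applyDPI(sel_ints, dpi_tolerance)
    gene_ints <- if (!is.null(map)) collapseToGenes(sel_ints, map)
                 else sel_ints
    net <- buildNetwork(gene_ints)
    networks[[ph]] <- net
    interactions[[ph]] <- ints
    metrics[[ph]] <- computeMetrics(net)
    nulls[[ph]] <- null
    cutoff_stats[[ph]] <- list(
      mi_at_cutoff = sel_ints$mi[k_use],
      p_value_at_cutoff = pValue(null, sel_ints$mi[k_use]),
      mi_threshold_at_p_report = miThreshold(null, p_report))
    if (!is.null(scan_grid))
      scans[[ph]] <- scanCutoffs(ints, scan_grid, map = map)
  }

  comparison <- NULL
  if (length(networks) >= 2) {
    comparison <- jaccardMatrices(networks)
    if (length(networks) <= 6)
      comparison$venn <- vennPartition(lapply(networks, nodeSet))
    if (!is.null(reference_phenotype) &&
        reference_phenotype %in% names(networks)) {
      cases <- networks[setdiff(names(networks), reference_phenotype)]
      comparison$core_set <- coreSet(
        lapply(cases, nodeSet),
        nodeSet(networks[[reference_phenotype]]))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenonet")),
    parameters = params,
    phenotypes = lapply(stats::setNames(labels, labels), function(ph)
      sum(phen == ph)),
    cutoff_statistics = cutoff_stats,
    network_summary = lapply(metrics, function(m)
      list(n_nodes = m$n_nodes, n_edges = m$n_edges,
           n_components = m$n_components,
           clustering_coefficient = m$clustering_coefficient_mean_local)),
    warnings = warnings_log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    for (ph in names(networks)) {
      f <- file.path(out_dir, paste0("edges_", ph, ".tsv"))
      writeEdges(edgeTable(networks[[ph]])[
        , c("source", "target", "weight")] |>
          stats::setNames(c("feature_a", "feature_b", "mi")), f)
      files <- c(files, f)
      f2 <- file.path(out_dir, paste0("network_", ph, ".sif"))
      writeSIF(networks[[ph]], f2)
      files <- c(files, f2)
    }
    f <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(manifest$network_summary, f, auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, f)
    if (!is.null(comparison)) {
      f <- file.path(out_dir, "node_jaccard.csv")
      utils::write.csv(comparison$node_jaccard, f)
      files <- c(files, f)
      f <- file.path(out_dir, "edge_jaccard.csv")
      utils::write.csv(comparison$edge_jaccard, f)
      files <- c(files, f)
    }
    manifest$checksums <- stats::setNames(
      unname(tools::md5sum(files)), basename(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  list(networks = networks, interactions = interactions, metrics = metrics,
       null_models = nulls, comparison = comparison, scans = scans,
       manifest = manifest)
}
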