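Package: phenonet
Title: Phenotype-Specific Transcriptional Network Inference and Comparison
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers phenotype-specific transcriptional co-expression
    networks from gene expression matrices using a Gaussian-kernel mutual
    information estimator with permutation-based significance calibration,
    and compares network architectures across phenotypes. Provides
    empirical-Bayes batch adjustment, cyclic loess renormalization and
    principal variance component analysis for multi-study comparability;
    top-K and MI-threshold edge selection with probe-to-gene collapsing;
    graph topology metrics (components, clustering coefficients, hubs, ego
    networks); Jaccard and Venn set comparison with core-set extraction;
    cutoff stability scans with random-graph baselines; and a synthetic
    expression generator with planted co-expression modules and batch
    effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    limma,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sva
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'synthgen.R'
    'preprocess.R'
    'mi.R'
    'network.R'
    'compare.R'
    'scan.R'
    'io.R'
    'pipeline.R'
    'phenonet-package.R'
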