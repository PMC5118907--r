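---
title: "phenonet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenonet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phenonet infers a co-expression network per phenotype from a gene
expression matrix, characterizes each network's topology, and compares the
architectures across phenotypes. The motivating application is
transcriptomic heterogeneity across disease subtypes — e.g. breast cancer
molecular subtypes versus non-tumor tissue — where the scientific question
is not only *which* genes participate in each phenotype's transcriptional
program but *how differently they are wired*. This vignette documents the
statistical machinery, its tunable parameters, the synthetic validation
cohort, and the design decisions taken where more than one defensible
choice existed.

## Mutual information estimation

The dependency measure between two expression profiles is mutual
information (MI), in nats. MI is zero exactly under independence and, for a
bivariate Gaussian with correlation $\rho$, equals
$-\tfrac12\ln(1-\rho^2)$ — the closed form the test suite uses as its
primary accuracy oracle.

`estimateMI()` is a Gaussian-kernel plug-in estimator:

$$\widehat{MI} = \frac1n \sum_{i=1}^n
  \log\frac{\hat j(x_i, y_i)}{\hat m_x(x_i)\,\hat m_y(y_i)},$$

with kernel density estimates of the joint ($\hat j$) and the marginals
($\hat m$) evaluated at the sample points themselves. Three choices shape
its behavior:

* **Copula transform (default on).** Each profile is first mapped to
  empirical normal scores, $z_i = \Phi^{-1}((r_i - \tfrac12)/n)$ with
  $r_i$ the rank. This makes the estimate exactly invariant under strictly
  monotone transformations of either variable (only ranks enter), removes
  any marginal-shape effect, and gives every feature an identical marginal
  sample so the marginal density term is cheap to reuse across the
  all-pairs computation. Normal scores are used rather than uniform
  $(0,1)$ ranks because kernel density estimation on a bounded interval
  suffers boundary bias that inflates MI; on the real line with Gaussian
  marginals there is no boundary.
* **Correlation-adaptive joint kernel.** The joint kernel covariance is
  $h^2\hat\Sigma$, where $\hat\Sigma$ is the sample covariance of the
  pair. A spherical product kernel oversmooths across the ridge of a
  strongly correlated pair and underestimates high MI by just about the
  test tolerance; letting the kernel follow the ridge removes that bias.
  Near-singular $\hat\Sigma$ (|r| > 0.9999, e.g. duplicated profiles) is
  shrunk to keep the kernel proper.
* **Bandwidth.** $h = c\, n^{-1/6}$, the Silverman rate for a
  two-dimensional Gaussian kernel, with marginal bandwidths $h \cdot sd$;
  the factor $c$ (default 1) is exposed in `miConfig()`.

Densities are evaluated *including* the self term. A leave-one-out variant
is slightly more accurate in absolute terms but clamps roughly half of all
null-pair estimates to exactly zero (its raw values are centered on zero
and negative estimates are clamped), which turns the permutation-null
p-value distribution into a point mass and breaks calibration. The plug-in
form is positively biased by a small, sample-size-dependent constant
(about +0.01–0.03 nats at n = 1000–5000) but is continuous under the null;
because every selection step (ranking, thresholds, p-values) is relative
to the same null, the constant cancels where it matters. Negative
estimates are still clamped to zero at the interface, and constant
profiles return 0 with a warning.

`allPairsMI()` computes all $N(N-1)/2$ unordered pairs in compiled code
(quadratic in sample count per pair), reports each pair once with
`feature_a < feature_b` under C collation, and orders output by descending
MI with lexicographic tie-breaks, so results are independent of feature
input order and of the session locale.

## Permutation null, p-values, thresholds

`buildNull()` estimates the null MI distribution for a given sample size by
permutation: for randomly sampled feature pairs, one profile is permuted
and MI recomputed; defaults are 200 pairs x 50 permutations, pooled into
one null of 10,000 values. Pooling across pairs is justified by the copula
transform: after rank normalization every profile has the same marginal
sample, so under permutation the null MI distribution depends on the pair
only through n. Per-pair nulls at the operating significance (p below
1e-10) would need more than 1e10 permutations and are infeasible; instead
the upper 5% of the pooled null is fit with an exponential tail (log
survival linear in MI, slope constrained negative by the class validity)
and `miThreshold(null, p)` extrapolates along that tail below the
empirical resolution 1/pool size. Within the empirical range the threshold
is the smallest pooled value whose survival is at most p. p-values from
`pValue()` are monotone nonincreasing in MI by construction.

## Network construction

The construction recipe for each phenotype: all-pairs MI on that
phenotype's samples only, keep the top-K interactions (`selectTopK()`,
deterministic ties), collapse probes to gene symbols (`collapseToGenes()`:
unmapped probes discarded, same-symbol pairs discarded as would-be
self-loops, duplicate gene pairs keep max MI and min p), and build a simple
undirected weighted graph (`buildNetwork()`). A threshold mode
(`selectByThreshold()` at `miThreshold(null, p)`) is exposed as the
alternative selection rule. Data-processing-inequality pruning
(`applyDPI()`) is available but off by default: the construction recipe
keeps top-ranked interactions as-is, and DPI is an optional post-filter
for users who want indirect-interaction removal.

## Topology metrics

`computeMetrics()` reports node/edge counts, the connected-component
census, the giant component, degree tables, the node-to-link ratio, and
*two* clustering coefficients: the transitivity (3 x triangles / connected
triples) and the mean local clustering coefficient with degree < 2 nodes
contributing zero and included in the mean. The mean-local value is the
headline number because it is what interactive network-analysis tools
report for a network-level "clustering coefficient", and reported subtype
network values in the literature follow that convention; the convention
for low-degree nodes is switchable (`include_low_degree = FALSE`). All
topology metrics ignore edge weights. Giant-component ties are broken by
edge count, then smallest node label, so results are deterministic.

igraph provides the graph primitives behind this surface; the test suite
checks components, triangles, both clustering conventions, degrees and
giant components against an independent brute-force enumeration on random
small graphs, exactly.

## Cross-phenotype comparison

Network similarity uses the Jaccard index on node sets (gene symbols) and
on edge sets (unordered symbol pairs, weights ignored). `vennPartition()`
assigns every gene of the union to exactly one of the $2^k - 1$ label
regions; `coreSet()` parameterizes the "present in every case network,
absent from the reference network" construction rather than hard-coding
any label set. Jaccard of two empty sets is defined as 1 (identical sets)
with a warning; real workflows never hit it. `crossNetworkDegree()`
tabulates per-gene degrees across networks with explicit absence flags,
and `egoNetwork()`/`inducedSubgraph()` extract the neighborhood and
core-subgraph views used to compare wiring of shared genes.

## Cutoff scanning and stability

Because the network is defined by a ranking cutoff, `scanCutoffs()`
rebuilds the network on a log-spaced grid of cutoffs (sharing one fixed
ranking, so edge sets are nested along the grid — asserted at run time)
and `selectByRatio()` picks the cutoff whose node-to-link ratio is nearest
a target, 0.1 by default — the regime characteristic of biological
complex networks, where nodes are far fewer than links.
`stabilityReport()` quantifies how much the architecture changes inside a
band around the selected cutoff: per-metric ranges and CVs, and per band
cutoff the node/edge Jaccard and degree-rank Spearman *against the
selected-K network*. The vs-selected convention matters: nested top-K
prefixes make the all-pairs Jaccard between the band extremes
$\approx K_{min}/K_{max}$ by construction, so an all-pairs summary would
measure the band width, not stability.

`randomBaselines()` contrasts an observed network with two seeded matched
ensembles: uniform random graphs with the same node and edge counts, and
degree-preserving edge-swap rewirings (10 x |E| attempted swaps per
replicate), reporting ensemble means, standard deviations and z-scores of
the observed clustering coefficients and component counts. Both ensembles
are provided because they control for different structure: (n, m) only,
versus the full degree sequence.

## Comparability preprocessing

For cohorts assembled from multiple studies, `combatAdjust()` implements
the parametric empirical-Bayes location/scale batch adjustment: gene-wise
standardization preserving covariate (phenotype) effects, per-batch
location and scale estimates shrunk toward normal / inverse-gamma priors
with method-of-moments hyperparameters, iterative posterior solution, and
return to the original scale. A single-batch input is returned unchanged;
batches of one sample are rejected (scale inestimable); constant genes
pass through with a warning. The implementation is validated against the
standard reference implementation to numerical identity in the test suite.
Two properties worth knowing: the EB posterior *shrinks*, so a shift that
is constant across genes is removed from the pooled signal while
individual genes retain residuals of the order of the shrinkage weight
times the sampling noise; and a second application is not an exact no-op —
it re-shrinks sampling noise — though it changes the data by under 5% of
what the first pass removed.

`cyclicLoessNormalize()` brings all samples to a common dynamic range by
pairwise MA-loess (degree-1 loess of per-pair difference vs average, half
the fitted difference moved between the columns, corrections averaged over
all pairs); the pairwise pass is delegated to limma and iterated until the
column-median drift falls below 1e-3 or `max_iter` (default 3) passes.
Span defaults to 0.7.

`pvca()` quantifies residual structure: principal components of the
sample-sample covariance are kept up to a cumulative-variance floor
(default 0.6), each component's score variance is decomposed across the
declared factors by method-of-moments one-way ANOVA (negative components
truncated at zero, remainder to the residual), and the per-factor
fractions are eigenvalue-weighted and renormalized to sum to one. The
method-of-moments route is deterministic and dependency-light; a
REML/mixed-model variant would differ in edge cases but not in the
before/after contrast the pipeline uses it for. Factors confounded 1:1
with sample id are rejected. The recommended recipe — adjust within
condition groups separately, renormalize together, check with PVCA before
and after — is a pipeline recipe (`runPipeline(preprocess = TRUE)`), not
hard-coded behavior.

## The synthetic validation cohort

`syntheticDesign()` / `generateExpression()` produce a cohort in which
every downstream claim can be checked against known ground truth. The
generative model:

* Per phenotype, genes of a module are an equicorrelated Gaussian block
  (compound symmetry): gene value $= \mu_g + \sigma\lambda_b
  (\sqrt\rho\, z_s + \sqrt{1-\rho}\,\varepsilon_{gs}) + \delta_b$, with a
  shared per-sample factor $z_s$ per module. Pairwise within-module
  correlation is exactly $\rho$ regardless of the noise scale, and the
  implied pair MI has the Gaussian closed form — the structure is chosen
  precisely so recovery and accuracy have analytic oracles.
* Batch artifacts are applied after the correlation structure: a per-batch
  location offset $\delta_b$ and a multiplicative factor $\lambda_b$ on
  the stochastic part — mirroring the location/scale model the adjustment
  stage removes.
* The probe layer expands genes into probes: each gene has a primary probe
  carrying its exact signal, a configurable fraction of genes gets 1–2
  replicate probes with independent probe noise (default sd 0.25), and a
  pool of extra pure-noise probes maps to no symbol. This exercises the
  discard/collapse rules with known answers.

Defaults describe the reference cohort used throughout the tests: 300
genes, three phenotypes of 150 samples each, twelve modules of ten genes
per phenotype at $\rho = 0.8$, module blocks staggered by 40 genes between
phenotypes so architectures overlap partially, two balanced interleaved
batches with no artifact (batch studies set `batch_shift`), baseline
intensities $\mathcal N(8, 1.5^2)$ on the log2 scale, unit noise. The
sizes keep every validation property — all-pairs MI over ~65,000 probe
pairs per phenotype, cutoff scans, ensembles — comfortably within minutes
on one CPU; they are the package's reference operating point, not a
limitation of the implementation, which is quadratic in features and
linear in samples-squared per pair.

What the generator does *not* emulate: probe-level hybridization physics,
heavy-tailed or skewed expression marginals (the copula transform makes
the estimator indifferent to them, but the generator does not test that
robustness), hub-dominated scale-free wiring (modules give block
structure, so degree distributions in the top-K regime are
planted-plus-noise rather than power-law), and correlated noise across
batches. Passing tests demonstrate correctness of the machinery under the
stated model, not performance guarantees on any particular real cohort.

## Numerical and interface conventions

* All orderings (edge orientation, tie-breaks, sort order) use C-collation
  radix ordering, so outputs are byte-identical across locales.
* Every stochastic stage takes an explicit seed; `runPipeline()` derives
  per-stage seeds deterministically from its global seed and records them
  in the manifest, together with md5 checksums of written artifacts. A
  rerun with the same inputs and seed is identical.
* Text formats are tab-separated with 17-significant-digit numerics, so a
  write/read round trip reproduces doubles exactly; readers validate field
  counts, self-loops and duplicates and report the offending line.
* Phenotypes with fewer than 10 samples are skipped with an explicit
  warning (kernel MI at n < 10 is not meaningful).
* The `n_permutations >= 100` guard applies to the pooled null size
  (pairs x permutations), which is what controls the empirical resolution.

## Known limitations

* The MI estimator's positive bias means absolute MI values should not be
  compared across different sample sizes; rankings and calibrated
  p-values should.
* The exponential tail extrapolation is a modeling assumption; at p =
  1e-10 the threshold is far outside the empirical pool and should be
  read as an operating point, not a validated quantile.
* PVCA here decomposes factors marginally (no interaction terms); strongly
  unbalanced or interacting designs deserve a mixed-model treatment.
* Core-set and Venn constructions are set operations on inferred node
  sets; they inherit all selection noise near the cutoff.
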