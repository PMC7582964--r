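---
title: "Meta-gene co-expression modules for recurrence prediction: methods and design"
author: "metamodule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-gene co-expression modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`metamodule` treats a bulk transcriptomic cohort as a gene × sample matrix
of log2-scale expression together with per-sample clinical annotation
(binary recurrence, ordinal WHO grade 1–3, optional Simpson grade 1–5,
time to recurrence and follow-up in years, cohort/batch label). The
working hypothesis is the standard weighted co-expression one: groups of
genes move together because they share latent regulatory programs, a
module's first principal component across samples (its *meta-gene*)
estimates that program's per-sample activity, and the programs — not
individual genes — carry the reproducible prognostic signal.

The pipeline has seven stages, each usable on its own: preprocessing
(log2, quantile normalization, cohort merging, batch correction), network
construction and module detection, meta-gene and kME computation,
phenotype association screens, the logistic recurrence classifier with
cross-validated and external evaluation, greedy module sparsification, and
gene-set over-representation analysis. Module *discovery* runs only on the
discovery cohort; validation cohorts receive gene lists and recompute
their own meta-genes, so no validation sample influences module
definitions.

# Preprocessing

`quantileNormalize()` forces every sample onto the vector of per-rank
cross-sample means, with ties receiving the mean of the reference values
at the tied ranks — the common microarray convention, delegated to
`limma::normalizeQuantiles(ties = TRUE)` and checked in the tests against
a hand-worked 3 × 2 example. `batchCorrect()` offers two modes:
`"eb-shrinkage"` (default) is ComBat's parametric empirical-Bayes model
via `sva::ComBat`, shrinking per-gene batch location/scale estimates
toward across-gene priors; `"location-scale"` is the transparent per-gene
standardize-and-restore fallback, which exactly preserves pooled per-gene
means. Because correction precedes, and is independent of, outcome
modeling, a covariate-preserving ComBat variant is unnecessary. Cohorts
are normalized per cohort, then merged on the gene intersection, then
batch-corrected; the stages stamp their outputs and refuse to run out of
order, since, e.g., a log2 transform of quantile-normalized data silently
corrupts every downstream correlation. An optional `medianScale()`
(per-array division by the 50th percentile) supports cohorts preprocessed
that way; it is not in the default chain.

# Network construction and module detection

The adjacency is unsigned by default, `a_ij = |cor|^β`. The sign mode is a
genuinely open choice — nothing in the method requires one — and unsigned
is both the historical default and the reading most consistent with
"correlations raised to a power"; `signMode = "signed"` is available.

β is selected by `pickSoftThreshold()`: for each candidate, per-gene
connectivity `k_i = Σ_{j≠i} a_ij` is binned into 10 equal-width bins,
`log10` frequency is regressed on `log10` mean bin connectivity, and the
smallest candidate with r² ≥ 0.9 *and negative slope* wins. Equal-width
binning is deliberate: equal-count bins would make the regression response
essentially constant (every bin holds the same number of genes) and the
fit statistic meaningless. When no candidate reaches the target — typical
for data without hub structure, including factor-model simulations — the
best-fitting candidate is returned flagged `targetMet = FALSE`, never
silently; callers who know their power (as in several tests here) pass it
explicitly.

The topological overlap matrix follows the standard formula
`TOM_ij = (Σ_{u≠i,j} a_iu a_uj + a_ij) / (min(k_i,k_j) + 1 − a_ij)`,
computed by one matrix product and checked against a literal triple loop.
`1 − TOM` is clustered with average linkage (`stats::hclust`).

`cutModules()` implements the core of the dynamic-hybrid cut. A branch is
accepted as a candidate cluster only when its top merge height falls below
a *core-scatter* bound interpolated between the dendrogram's 5th-percentile
height and the cut height (`maxHeight = 0.99` of the height range);
`deepSplit` 0–4 moves the interpolation fraction from 0.64 to 0.96, so
higher values accept looser branches and yield more, smaller modules. A
sub-`minSize` side branch joining a candidate far above the candidate's
own top (more than half the complementary scatter margin) is peeled off
rather than absorbed — this is what keeps unstructured genes out of
modules when the assignment stage is disabled. Branches of at least
`minSize = 20` genes become modules, ordered by size and named by the
conventional color sequence (turquoise, blue, ...); everything else is
pooled. Stage 2 (`pamStage = TRUE`) assigns each pooled gene to the module
with the smallest average dissimilarity when that module is strictly
closest, leaving the rest `"unassigned"`. With the assignment stage on,
nearly all genes end up in modules (the expected behavior on arrays
designed around correlated gene panels); with it off, noise genes
predominantly stay unassigned — both behaviors are exercised in the tests.

# Meta-genes and kME

Module member rows are z-scored per gene, the first right singular vector
gives per-sample scores, scaled to unit variance and sign-oriented so the
meta-gene correlates positively with the mean standardized module profile.
The orientation makes signs comparable across cohorts; a module whose
expression is globally negated still satisfies the invariant. Zero-variance
genes are dropped from the PCA with a message; a module left with fewer
than two usable genes is an error, not a silent scalar. `varExplained`
reports the first component's share of the standardized module variance.

Module gene lists transfer across cohorts; meta-genes are recomputed as
PC1 within each cohort. The alternative — projecting discovery loadings
onto new cohorts — is implemented (`projectMetagenes()`) because strict
cross-validation needs it, but cross-cohort evaluation defaults to
recomputation: platform differences make frozen loadings brittle, and the
orientation rule keeps recomputed signs consistent.

# Association screens

Recurrence screens use the Welch t-test (`varEqual = TRUE` gives the
pooled variant); where the method description says only "t-test", unequal
variances are the safer default. Degenerate input (zero variance in both
groups, equal means) is reported as t = 0, p = 1 by convention rather
than erroring mid-pipeline. Grade association is one-way fixed-effects
ANOVA. Time-to-recurrence correlation offers two modes:
`"year-binned"` (default) averages the meta-gene within integer years of
time-to-recurrence (bins with ≥ 3 samples) and correlates bin means with
bin years — the mode that produces the smooth, high-magnitude trend
correlations typical of published figures — while `"per-sample"`
correlates raw values. Both are exposed because the binned presentation
is a declared choice, not an inference about how any particular figure
was computed.

The TF marker screen is a strict AND-rule: enrichment q < 0.05, own-gene
t-test p < 0.05 in *every* supplied validation cohort, consistent
direction across cohorts; grade-ANOVA p-values are reported alongside.
The intra-chromosomal linkage screen correlates genomic separation with
pairwise co-expression over same-chromosome gene pairs and derives a
two-sided p from seeded permutations of the gene-to-position assignment.

# Classifier and evaluation

`fitLogistic()` is maximum-likelihood IRLS via `stats::glm` with Wald
CIs; complete separation and non-convergence are detected and flagged.
Odds ratios are per meta-gene standard deviation (meta-genes are
unit-variance by construction) — a declared scale convention, so OR
magnitudes are comparable across modules and cohorts but not to analyses
using unscaled summaries. WHO and Simpson grades enter models as numeric
ordinals; samples missing a covariate are dropped from that model only.

ROC/AUC and DeLong machinery delegate to `pROC` (AUC as the Mann–Whitney
statistic with half credit for ties, DeLong structural-components
variance, paired correlated-curve test); the score direction is pinned so
AUC below 0.5 is reported as-is, and rank-identical score pairs
short-circuit to z = 0, p = 1 exactly rather than 0/0.

Cross-validation is stratified, seeded, and *strict by default*: per
fold, meta-gene centers, scales and loadings come from the training
samples only, and held-out samples are projected onto them. The
`"whole-cohort"` compatibility mode — meta-genes computed once on all
samples, only the logistic coefficients cross-validated — exists because
it is a plausible reading of how such pipelines are often run; an
adversarial test in the suite constructs data whose outcome signal lives
in fold-local expression directions and shows the compatibility mode
leaking (folded AUC far above chance) while strict mode stays at chance.
That demonstration is why strict is the default. Per-grade stratification
deliberately uses whole-cohort meta-genes and subsets at evaluation, since
a stratum is a read-out of one fitted model, not a new training set.

# Sparsification

`sparsifyModule()` ranks module genes once by individual folded AUC
(`max(AUC, 1 − AUC)`; module genes may correlate negatively with the
meta-gene, and the unfolded value is reported alongside), then removes
genes in that static order, recomputing the remaining module's meta-gene
AUC after each removal, until the AUC drops below `threshold = 0.90` of
the full module's folded AUC, `cap = 100` removals are reached, or fewer
than two genes remain. The sparse module is the removals up to and
including the threshold-crossing one (`inclusive = FALSE` excludes it;
the counting convention is genuinely ambiguous in prose descriptions of
this procedure, so both are provided). Re-ranking survivors after each
removal is available via `rerank` but is not the default: a fixed
descending order is the plain reading of "in descending order of highest
AUC". A module whose full folded AUC does not exceed `minFullAUC = 0.55`
is rejected as non-predictive — the folded AUC of pure noise already sits
at 0.5, so a threshold exactly at 0.5 would never fire.

# Enrichment

Over-representation is the hypergeometric upper tail
`P(X ≥ k)` with Benjamini–Hochberg adjustment across the library's terms,
matched case-insensitively. The universe defaults to the genes present on
the platform/matrix, not the genome: on a small cancer-focused array the
universe choice materially changes every p-value, and the platform
universe is the defensible null for "is this module enriched relative to
what was measured".

# The synthetic-data generator

`simulateCohort()` draws per-module latent factors f_m ~ N(0,1)
independently across modules — the minimal generative model consistent
with PCA meta-genes — and gene expression
`mu_g + lambda_g f_m + eps`, `eps ~ N(0, sigma^2)`, with per-gene
baselines mu_g ~ N(8, 1.5²) on the log2 scale. Defaults emulate the
modeled study's discovery conditions: 252 samples; two planted modules of
220 and 299 genes among 912 total (a cancer-focused array); loadings
drawn uniformly from [0.6, 1] so module membership strength varies as
real kME distributions do; sigma = 1. Recurrence is
Bernoulli(plogis(−0.85 + 2.5 f_pred)) on the second module's factor,
giving a recurrence rate near 0.37 and a theoretical factor AUC near 0.90
(`theoreticalAUC()` computes it by seeded 2×10⁶-draw Monte Carlo). WHO
grade follows an ordered logit on the same factor with cutpoints (0.35,
2.9) and slope 1.5, approximating a 56/35/9% grade split; time to
recurrence is `exp(1.1 − 0.35 f + N(0, 0.25²))` years truncated to the
follow-up window (uniform 1–15 years), so its median sits near 3 years
and it declines with the predictive factor. Batch effects are additive
per-gene shifts N(batchShift, batchShiftSD²) and log-normal
multiplicative scales. `simulateMultiCohort()` shares gene identities,
loadings and baselines across cohorts (they are gene properties) while
samples, outcomes and batch offsets are cohort-specific.

What the generator does *not* emulate: probe-level noise physics,
saturation, count-level RNA-seq sampling, correlated module factors,
nonlinear outcome links, censoring mechanics beyond truncation, or
annotation errors. Passing tests therefore certify the pipeline's
statistical machinery on data satisfying its own assumptions — module
recovery, meta-gene fidelity, AUC recovery, leakage control — not
performance on any real cohort.

# Numerical choices and degenerate inputs

Duplicate probe rows collapse to the maximum-variance row (configurable
to mean). Quantile-normalization ties average the reference values at
tied ranks. Zero-variance genes: error by default in the network (or
dropped on request), dropped from PCAs, NA in kME, scale-step skipped in
location-scale batch correction — always with a message. Stratified fold
ties are broken by a seeded shuffle; identical inputs give identical
partitions, folds and reports. Empty gene intersections, single-class
outcomes, single-grade ANOVA, sub-3-point correlations and missing
regressors are errors naming the offending unit.

# Problem sizes in the test suite

The suite verifies oracle equivalence on exhaustive small cases (1000
random AUC instances vs pair counting; 200 random TOMs vs the triple
loop) and statistical behavior at sizes chosen for stable Monte-Carlo
margins: module recovery over 20 seeds at n = 150 with 60/40-gene
modules at sigma = 0.4; DeLong null calibration over 1000 simulations at
n = 300; logistic recovery over 500 replicates at n = 2000; the
leakage demonstration at n = 1200 with a 120-gene module; sparsification
signal isolation at n = 2000 with a 50-gene module whose three strong
genes (loading 1.0) sit over a weak shared background (loading 0.10) —
sized so the background factor keeps the meta-gene informative while any
strong gene remains, and collapses when the last one is removed; and ten
end-to-end study replicas at cohort sizes 250/110/145.

# Known limitations

Single-block network construction only (no block-wise approximation for
very large gene sets); no consensus networks or module-preservation
statistics; no survival modeling (time-to-recurrence is used only
descriptively); no regularized classifiers or calibration analysis;
enrichment is over-representation only, not rank-based. The hybrid tree
cut implements the core shape criteria of the dynamic-hybrid method, not
every refinement of the reference implementation, and on dendrograms
whose height range is strongly compressed (very high soft-threshold
powers) module detection degrades — the flagged power selection is the
early warning for that regime.
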