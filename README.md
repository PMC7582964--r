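# metamodule

Co-expression meta-gene modules for predicting tumor recurrence from bulk
transcriptomics.

Histological grading predicts meningioma recurrence poorly: a substantial
fraction of completely excised low-grade tumors still recur, so patients
face lifelong imaging surveillance. `metamodule` implements a weighted gene
co-expression approach to this problem for computational biologists and
biostatisticians working with gene × sample expression cohorts: it
discovers co-expressed gene modules in a discovery cohort, compresses each
module into a one-number-per-sample **meta-gene**, and uses the meta-genes
as regressors in a logistic recurrence classifier that is cross-validated
and then re-evaluated on independent validation cohorts using the same
module gene lists.

## The model

Starting from a log2-scale expression matrix, the package:

1. builds a soft-thresholded adjacency `a_ij = |cor(x_i, x_j)|^β`, with β
   the smallest natural number whose degree distribution approaches
   scale-free topology (log–log regression r² ≥ 0.9, negative slope);
2. converts it to the topological overlap matrix

   `TOM_ij = (Σ_{u≠i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,

   clusters `1 − TOM` with average linkage, and detects modules by a
   hybrid adaptive tree cut (branch shape criteria plus nearest-module
   assignment of stragglers);
3. summarizes each module by its first principal component across samples
   (the meta-gene, unit variance, sign-oriented against the mean module
   profile), and reports per-gene module membership `kME = cor(x_g, PC1)`;
4. screens modules for association with recurrence (Welch t-test), WHO
   grade (one-way ANOVA) and time to recurrence (Pearson correlation);
5. fits `logit P(recurrence) = β0 + Σ_m β_m · metagene_m (+ WHO grade,
   Simpson grade)`, evaluated by stratified 10-fold cross-validation
   (meta-gene loadings re-estimated per training fold), external
   validation, per-grade strata, and DeLong tests between correlated ROC
   curves;
6. sparsifies a module by iteratively removing its most individually
   predictive genes (descending single-gene AUC) while recomputing the
   meta-gene, stopping when the AUC drops below 90% of the full module's;
7. runs Fisher-exact (hypergeometric) over-representation analysis against
   GMT gene-set libraries, with a transcription-factor marker screen
   requiring enrichment q < 0.05 and consistent differential expression in
   every validation cohort.

A synthetic-data module generates multi-cohort expression with planted
module factors, a logistically module-driven outcome, ordinal grade,
time-to-recurrence and batch effects, plus the ground truth needed to test
every stage.

## Worked example

```r
library(metamodule)

# two cohorts sharing two planted modules (the second drives recurrence)
specs <- list(
  syntheticCohortSpec(nSamples = 200, moduleSizes = c(60, 80),
                      nNoiseGenes = 60, sigma = 0.8, beta1 = 2.5, seed = 11),
  syntheticCohortSpec(nSamples = 120, moduleSizes = c(60, 80),
                      nNoiseGenes = 60, sigma = 0.8, beta1 = 2.5,
                      batchShiftSD = 0.5, seed = 12))
sims <- simulateMultiCohort(specs, prefixes = c("disc", "val"))

report <- runPipeline(sims[[1]]$cohort,
                      validation = list(val = sims[[2]]$cohort),
                      power = 6, seed = 1)

report$partition
#> ModulePartition over 200 genes
#>   2 modules: turquoise (110), blue (90)
#>   unassigned: 0
report$cv$roc
#> ROC: AUC = 0.884 +/- 0.023 (76 pos / 124 neg)
report$external$val$roc
#> ROC: AUC = 0.923 +/- 0.024 (51 pos / 69 neg)
report$multivariate$discovery
#> Logistic model (2 regressor(s))
#>                coef      OR  CI.lo   CI.hi      p
#> (Intercept) -1.3960  0.2476 0.0860  0.7131 0.0097
#> turquoise    2.3631 10.6236 4.9468 22.8152 0.0000
#> who_grade    0.2898  1.3362 0.7229  2.4701 0.3552
```

The partition shows the two recovered modules (named by size, WGCNA color
convention; the 80-gene planted module plus absorbed stragglers becomes
`turquoise`). The cross-validated AUC (0.88 ± SE by DeLong) measures
discovery-cohort discrimination from pooled out-of-fold probabilities; the
external AUC applies the discovery-trained model to the validation
cohort's own recomputed meta-genes. The multivariate table reports the
module's odds ratio per meta-gene standard deviation with WHO grade
controlled: here the module stays a strong independent predictor (OR 10.6,
p < 1e-4) while grade adds nothing beyond it, mirroring how such a module
would be read in a clinical-transcriptomic study. The module's recurrence
t-test (p ≈ 3e-23, direction "up") and its time-to-recurrence correlation
(ρ ≈ −0.93: higher meta-gene, earlier recurrence) come from
`report$associations`.

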