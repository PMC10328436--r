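# survGCCA

Outcome-guided molecular subtyping from multi-omics data, in two stages:

1. **Clustering.** Each -omics view (gene expression, promoter methylation,
   miRNA abundance, ...) is passed through its own two-layer neural network,
   and the networks are trained jointly under a **generalized canonical
   correlation analysis (GCCA)** objective

   min over U_v, G of Σ_v w_v ‖ G − U_vᵀ f_v(X_v) ‖²_F subject to G Gᵀ = I,

   where X_v ∈ R^(d_v×N) is view v, f_v its network, and G ∈ R^(r×N) the
   shared representation whose columns summarize each patient across all
   views. Samples with missing views are retained and handled by masking.
   The r embedding coordinates are then filtered by univariate Cox
   proportional-hazards significance (score test, P < 0.05), the filtered
   embedding is clustered with k-means (100 restarts, 2000 iterations), the
   number of clusters is chosen by the Calinski–Harabasz score with a
   silhouette tie-break, and the prognostic separation of the resulting
   subtypes is quantified with Kaplan–Meier curves and the log-rank test.

2. **Classification.** To call the discovered subtypes on new cohorts —
   including cohorts measured on a different platform — a per-omics
   classifier is trained on the original feature matrix: median scaling,
   standardization of external data to the training moments, equal-frequency
   discretization into ranked bins (external samples are placed into the
   *training* bins, never re-binned), random-forest recursive feature
   elimination with repeated cross-validation, and a gradient-boosted tree
   ensemble tuned by Bayesian (sequential model-based) optimization.

The package is aimed at computational biologists who want survival-aware
multi-omics subtypes that (a) use every patient, even those missing one or
two assays, and (b) travel across cohorts and platforms via rank-preserving
discretization. A synthetic-cohort simulator with planted, survival-linked
subtype structure, missing views and platform-shifted external cohorts makes
every stage testable without any data download.

## Worked example

Discover subtypes on a simulated cohort of 300 patients with three views
(2000 / 1500 / 200 features), 10% missing views, two planted subtypes with a
hazard ratio of 3 between them:

```r
library(survGCCA)

cohort <- simulateCohort(simulationConfig(seed = 1))
model  <- trainDgcca(cohort@dataset, viewNetworkConfig(), gccaConfig(seed = 1))
emb    <- embedSamples(model, cohort@dataset)            # 300 x 100

flt <- filterEmbedding(emb, survivalTable(cohort))       # Cox filter
sum(flt$results$selected)
#> [1] 4

sel  <- selectK(flt$embedding, 2:6, seed = 1)
sel$kBest
#> [1] 2
best <- sel$models[["k2"]]
logrankGroups(clusterLabels(best), survivalTable(cohort))
#> Log-rank test: chi2 = 47.45 on 1 df, p = 5.642e-12

mclust::adjustedRandIndex(clusterLabels(best), cohort@trueLabels)
#> [1] 0.8214478
```

Four of the 100 embedding coordinates pass the Cox filter; k-means on them
selects k = 2, recovers the planted subtypes at ARI 0.82, and the two
subtypes separate sharply in survival (log-rank P = 5.6e-12).

Transfer the subtypes to an external cohort measured on a shifted platform
(65% feature overlap, per-feature monotone warp):

```r
ext   <- simulatePlatformShift(cohort, viewIndex = 3, overlapFrac = 0.65,
                               seed = 2)
vw    <- views(cohort@dataset)[[3]]
feats <- intersectFeatures(vw, ext$view)                 # 130 of 200
x <- t(viewValues(vw)[feats, ]); y <- factor(cohort@trueLabels[rownames(x)])
scaler <- fitScaler(x)
z      <- standardizeExternal(x, scaler)
bins   <- fitBins(z, 30)
b      <- applyBins(bins, z)
fs  <- rfRfeSelect(b, y, seed = 1)                       # 10x10 CV RFE
clf <- tuneTrainClassifier(b[, fs@chosenFeatures], y, budget = 20, seed = 1,
                           scaler = scaler, bins = bins)
preds <- predictSubtypes(clf, ext$view)
mean(preds$subtype == as.character(ext$labels[preds$sample_id]))
#> [1] 0.9166667
logrankGroups(preds$subtype, ext$survival)
#> Log-rank test: chi2 = 27.94 on 1 df, p = 1.25e-07
```

The classifier keeps 17 of 130 shared features, calls the external cohort at
92% accuracy against the planted truth, and the predicted subtypes reproduce
the survival separation (log-rank P = 1.2e-07).

The same analyses are available through `runClusterStage()`,
`runClassifyStage()`, `runValidateStage()` and `runSimulate()` driven by a
single YAML configuration, or from a shell via
`inst/scripts/subtype-pipeline.R {simulate|cluster|classify|validate}`.

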