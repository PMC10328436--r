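---
title: "Outcome-guided multi-omics subtyping with survGCCA: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outcome-guided multi-omics subtyping with survGCCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`survGCCA` treats each -omics modality measured on a patient cohort as one
*view* of a common biological state. Given V views $X_v \in
\mathbb{R}^{d_v \times N}$, per-view two-layer networks $f_v$ and a shared
representation $G \in \mathbb{R}^{r \times N}$, the clustering stage solves

$$\min_{U_v,\,G}\; \sum_{v=1}^{V} w_v\, \| (G - U_v^\top f_v(X_v))\, D_v
  \|_F^2 \quad \text{s.t. } G G^\top = I,$$

where $D_v$ restricts to the samples actually measured in view $v$. The
inner minimization over $U_v$ and $G$ has a closed form: with
$Y_v = f_v(X_v)$ centered per row over present samples,
$C_v = Y_v Y_v^\top + \rho I$ and
$P_v = Y_v^\top C_v^{-1} Y_v$, the objective at the optimal $U_v$ equals
$\operatorname{tr}\!\big(G\, (D - M)\, G^\top\big)$ with
$M = \sum_v w_v P_v$ and $D$ the diagonal matrix of per-sample view
availability $\sum_v w_v \mathbf{1}[\text{present}]$. The networks are
trained by full-batch gradient descent through this solve (the gradient at
the optimum is $2 w_v (U_v U_v^\top Y_v - U_v G)$, pushed through the
centering operator), with L1/L2 penalties on the weight matrices.

Two properties of this objective shape everything downstream:

* **Correlation, not covariance.** $P_v$ is (up to the ridge $\rho$) a
  projector onto the row space of $Y_v$, so the eigenvalues of $M$ measure
  *how consistently* a sample-space direction appears across views — never
  how large it is. A planted subtype separation of 8 latent standard
  deviations earns the same eigenvalue as one of 0.8; what distinguishes
  directions is their cross-view reproducibility and their per-view
  signal-to-noise. Consequently the method can only concentrate a subtype
  signal into few embedding coordinates when that signal is among the
  *dominant shared components*, which is exactly the regime the simulator's
  defaults emulate.

* **The low-rank truncation is the denoiser.** With $d_v \gg N$ the raw row
  space of a view is all of $\mathbb{R}^N$ and every direction would look
  perfectly "shared". Truncating each view to its top `viewRank` variance
  modes (default 100, matching the output layer width) is what re-introduces
  variance information and makes the projector meaningful.

## Missing views

Patients missing a view contribute zero columns to that view's $Y_v$, are
excluded from its covariance and residual, and re-enter through the other
views. The eigenproblem is solved on $D - M$ (bottom-$r$ eigenspace), not on
$M$ alone: the two coincide exactly for complete data, but for incomplete
data only $D - M$ is consistent with the objective above. The distinction
matters in practice — ranking by eigenvalues of $M$ penalizes samples for
*how many* views they have rather than for how well their views agree, which
measurably shrinks incomplete samples' embedding rows and degrades the
label fidelity of the subtype coordinate on the reference fixture (0.92 to
0.81 correlation at 10% missing views).

## Outcome filter and clustering

Each of the r embedding coordinates is tested as the sole covariate of a
univariate Cox proportional-hazards model (Efron ties); the score test of
$\beta = 0$ is used because for a group indicator it is identical to the
log-rank test. Coordinates with $P < \alpha$ (default 0.05) are kept with no
multiple-testing correction, matching the per-coordinate rule the method is
built around (a Benjamini–Hochberg option exists but is off by default).
k-means (Lloyd's algorithm, uniform random data-point initialization, best
inertia of 100 restarts, 2000 iterations) clusters the filtered embedding;
an empty cluster is reseeded at the sample farthest from its centroid. The
number of clusters maximizes the Calinski–Harabasz score over k = 2..6, with
ties broken by higher average silhouette, then smaller k; the diagnostics
table also reports the fraction of negative per-sample silhouette widths so
that the usual visual silhouette-plot inspection has a mechanical,
reproducible counterpart.

The k-means engine is implemented in the package rather than delegated, so
that the empty-cluster reseeding contract and restart semantics are exact;
`stats::kmeans` agrees with it on non-degenerate inputs and the planted
fixtures recover their generating partition exactly.

# Cross-platform classification

The classification stage never sees the embedding: it works on one original
view so the resulting classifier can be applied to any cohort measuring
those features. The preprocessing chain is fitted on training data only and
stored on the classifier:

1. **Median scaling** — per-feature subtraction of the training median
   (`fitScaler(..., method = "divide")` selects the divide-by-median variant
   instead; centering is the default reading).
2. **Standardization to training moments** — external values are centered
   with the *training* median and standardized by the *training* mean and
   standard deviation of the scaled matrix. Zero-spread features pass
   through centered, with a message.
3. **Equal-frequency binning** — interior cut points at the i/B quantiles
   (linear interpolation) of the scaled training values; bins are fit on the
   standardized training matrix and external samples are *placed into the
   training bins*, never re-binned, so external calls live on the training
   scale. Ties merge edges deterministically. B is a tuning choice; 30
   (finer) and 15 (coarser) are the offered defaults.
4. **RF-RFE** — within each fold of a repeated stratified CV (10 folds, 10
   repeats), features are ranked by random-forest impurity importance and
   nested subsets on a halving grid are scored on the held-out part. The
   chosen size is the smallest whose mean accuracy is within one *standard
   error* of the best (the CART/glmnet one-standard-error rule). The raw
   resample standard deviation is deliberately not used as the band: with
   10x10 CV at a few hundred samples it is several times the dynamic range
   of the whole RFE curve, which would always select a single feature and
   produce brittle single-marker classifiers that transfer poorly.
5. **Boosted trees with SMBO tuning** — the search space is fixed and
   documented (`eta` log-uniform 0.01–0.3, depth 2–8, 50–300 rounds,
   row/column subsampling 0.5–1, minimum child weight 1–10); a Latin
   hypercube design seeds a Gaussian-process surrogate (RBF kernel on the
   unit cube, length-scale 0.3) whose expected improvement proposes the next
   configuration, each scored by mean stratified 10-fold CV accuracy
   (accuracy is the tuning objective; AUC — one-vs-rest macro for k > 2 — is
   recorded alongside). Default budget: 50 evaluated configurations. The
   optimizer is implemented in the package (a GP-EI loop is ~60 lines);
   no installed dependency provides sequential model-based optimization.

Monotone per-feature platform distortions are absorbed by the rank-based
binning as long as the standardization brings external values onto the
training scale; bin assignments of training data are provably invariant
under any strictly increasing per-feature transform applied before fitting.

# The simulator

`simulateCohort()` draws, per sample, a cluster id (uniform over K) and a
latent factor $h \sim \mathcal{N}(\mu_k, I)$ with cluster means at scaled
simplex corners separated by `clusterSeparation` (in latent-sd units). View
v observes $A_v\,\mathrm{softplus}(B_v h)$ plus Gaussian noise on its
shared-signal features and pure noise elsewhere; the softplus makes the
view maps nonlinear, so a nonlinear shared representation has headroom over
a purely linear one. Survival is exponential with hazard
$\lambda_0\, \mathrm{HR}^{k-1}$, censoring is independent uniform with its
window calibrated by root-finding so the expected censored fraction hits the
target; views are dropped independently per sample, always keeping at least
one. `simulatePlatformShift()` redraws a fresh cohort from the *same* mixing
matrices, keeps a random `overlapFrac` of one view's features and applies
the strictly monotone warp $x \mapsto a x + b + c \tanh x$ with
$|c| \le \texttt{warpStrength}\cdot a < a$.

Reference conditions (the package defaults, used by the test suite and
`scripts/acceptance.R`): n = 300, K = 2, view dimensions 2000/1500/200
(emulating genes / promoter methylation / miRNAs), latent dimension 10,
separation 8, 20% shared-signal features per view, noise sd 0.5, 10% missing
views, hazard ratio 3, baseline hazard 1e-3 per day, 50% censoring. The
separation is deliberately large: given the scale-blindness discussed above,
"strong shared signal" must mean "dominant among the shared components" for
the planted subtype to occupy a leading embedding coordinate.

What the simulator does **not** emulate: library-size effects, beta-value
bimodality, feature-feature correlation beyond the shared latent, batch
structure within a cohort, or informative censoring. Passing tests therefore
demonstrate the pipeline's statistical machinery, not robustness to every
real-data pathology.

# Numerical choices

* **Learning rate** 1e-3, full batch, 20 epochs. Larger steps (1e-2) are
  numerically stable here but behave badly statistically at desk scale: with
  r equal to the output width the objective rewards aligning *all* output
  directions across views, and aggressive steps let the networks align
  view-specific noise within 20 epochs, collapsing the eigengap between
  genuinely shared components and the chance-overlap noise band
  (every eigenvalue of M approaches V, and the subtype coordinate is
  scrambled across the embedding). A conservative rate refines the objective
  while preserving that spectral separation. A non-finite loss aborts with
  the epoch and a rate suggestion.
* **Output layer is linear**; hidden activation is ReLU by default (tanh
  and identity available). This keeps the GCCA loss on an unconstrained
  range.
* **Centering** of each view's outputs over its present samples happens
  inside every solve; covariance-based CCA is undefined without it.
* **Eigenvector signs** are fixed first-nonzero-positive; eigenvalue ties
  keep the decomposition's index order — both purely for reproducibility.
* **Penalty convention**: L1 adds $l_1\,\mathrm{sign}(W)$ and L2 adds
  $2 l_2 W$ to weight gradients; biases are unpenalized.
* **Degenerate inputs**: constant features get Cox p = 1 (never selected);
  k = N clustering reports silhouette NA with a warning; zero-variance
  clusters give an infinite Calinski–Harabasz score (perfect separation);
  constant features collapse to a single bin.
* **Problem sizes in the test suite** mirror the reference conditions
  (n = 300 cohorts for the end-to-end and transfer checks; smaller planted
  cohorts for orchestration determinism), chosen so each stage is exercised
  at the scale its statistical behavior is claimed.

# Known limitations

* With K = 2 the between-cluster variance expressible across the orthonormal
  embedding coordinates is bounded by one coordinate's worth, so every
  false-positive coordinate admitted by the per-coordinate 0.05 filter
  dilutes k-means geometry; recovery is reliable only when the subtype
  coordinate carries label correlation around 0.9 or higher, which the
  reference conditions provide. Cohorts with weaker or highly diffuse
  signal will need the BH filter option or a smaller embedding.
* The availability-consistent eigenproblem removes the systematic bias for
  incomplete samples, but their embedding rows are still estimated from
  fewer views and correspondingly noisier.
* Standardizing external cohorts by the *training* moments is the stated
  transfer contract; it aligns scales only up to a global per-feature
  affine, so platforms whose distortions are large and feature-specific
  rely on the binning's rank robustness and on ensembling over multiple
  features (one reason the one-standard-error rule, not a single best
  marker, sizes the model).
* The GP-EI tuner is a simple SMBO implementation: fixed length-scale, no
  marginal-likelihood optimization; adequate for the 6-dimensional space
  and 50-evaluation budgets it serves.
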