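---
title: "Connectome-based diagnostic modelling: methods and design"
author: "conndiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based diagnostic modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package does

`conndiag` implements a complete, testable pipeline for diagnostic
classification and biomarker discovery from functional-connectome and
anatomical features: tangent-space embedding of subject connectivity
matrices, a twelve-family model zoo searched by unbiased random
hyperparameter draws over frozen stratified splits, permutation feature
importance (PFI) calibrated against a label-permutation null with
Benjamini–Yekutieli (BY) false-discovery control, consensus biomarker
ranking across top models, hyperparameter-landscape analysis, and
external-cohort transfer with supervised domain adaptation.

Because the motivating application (autism-spectrum-disorder vs typically
developing classification from resting-state fMRI) requires large imaging
datasets, every stage is exercised here on synthetic cohorts with planted
ground truth. The synthetic generator is first-class, tested code: it
defines the study conditions under which the pipeline's statistical
properties are verified.

# The feature model

Each subject contributes a T × R matrix of ROI timeseries. Its R × R
covariance is estimated with analytic (Ledoit–Wolf-style) shrinkage toward
the diagonal, which keeps the estimate symmetric positive definite (SPD)
even when T < R. The shrinkage intensity is data-driven by default and can
be fixed (`shrinkage = 1` returns the diagonal exactly).

Connectivity is represented in the tangent space of the SPD manifold at
the training population's geometric mean. The reference G is the Fréchet
mean under the affine-invariant metric, computed by the standard
fixed-point iteration

G ← G^{1/2} expm( mean_i logm(G^{−1/2} C_i G^{−1/2}) ) G^{1/2}

with tolerance 1e−7 on the Frobenius norm of the mean whitened log,
at most 200 iterations, and step halving when the residual increases. A
subject's embedding is logm(W C Wᵀ) with W = G^{−1/2}; the strict upper
triangle (row-major, diagonal excluded, no √2 rescaling of off-diagonal
entries) is flattened into edge features named `edge_i_j`. Feature sets
are assembled as [functional | anatomical | sex | site one-hot]; all
modes carry the sex and site covariates. Standardization uses means and
standard deviations of a designated fit population only; constant columns
are flagged and zeroed rather than divided.

Two artifacts — the tangent reference and the scaler — are frozen after
fitting and carry MD5 checksums. Inside cross-validation they are refit on
each fold's training portion (leakage-safe default; a global mode refits
once on the full training set). External cohorts are always embedded and
scaled with the *source* artifacts; models store the checksums they were
trained with and transfer evaluation hard-errors on any mismatch.

# The model zoo and the search protocol

Twelve families sit behind one fit/score contract: three classical linear
(linear-kernel SVM, lasso- and ridge-penalized logistic regression), six
classical nonlinear (Gaussian naive Bayes, random forest, extremely
randomized trees, adaptive boosting, gradient boosting, Gaussian-kernel
SVM) and three neural (dense feedforward, bidirectional LSTM, and an
edge-to-edge connectome CNN that accepts only square connectivity input).
Search spaces are data, not code (`inst/extdata/model_spaces.json`), with
the published ranges: estimators [50, 5000], max nodes [5, 50], C
[1e−4, 1e5] (SVMs) or [1e−4, 1e4] (logistic), gamma [1e−2, 1e2],
max iterations [1e4, 1e5], gradient-boosting learn rate [0.1, 0.9], depth
[1, 10], subsampling [0.2, 0.8], columns per tree [0.2, 1]; dense/LSTM
hidden layers [1, 3], initial width [16, 256], dropout [0.1, 0.6], L2
[1e−4, 2e−2]; connectome-CNN blocks [0, 2], width [16, 64], leaky slope
[0.1, 0.5]. Dimensions spanning two or more decades (estimators, max
iterations, C, gamma, L2) are drawn log-uniformly; integers are rounded
after the draw. The adaptive-boosting learning-rate range of [5, 50] is
atypical but kept as published; `adaboost_conventional_lr = TRUE`
substitutes a conventional [0.01, 1] log-uniform range.

Classical families delegate to established implementations (e1071,
randomForest, ranger, xgboost, glmnet). Two wrinkles: ranger exposes tree
depth rather than a node cap, so the max-nodes dimension maps to
`max.depth = ceiling(log2(nodes + 1))`; and libsvm runs to its own
convergence, so the max-iterations dimension is recorded in the
configuration but not enforced for the SVMs. Adaptive boosting has no
suitable installed implementation and is a hand-written discrete
stump booster whose per-round weight is alpha = lr · ½·log((1−err)/err),
with thresholds found by vectorized weighted cumulative sums.

The three neural families are implemented in a compact engine written in
base R with hand-derived backpropagation, verified against numerical
differentiation to ~1e−11 in the test suite. All train with Adam
(learning rate 1e−3), minibatches of 32, binary cross-entropy with L2
weight decay, inverted dropout, at most 100 epochs, and early stopping
(patience 10) monitored on the CV fold's validation portion — or, when
refitting on the full training set, on an internal stratified 10%
carve-out. The decision layer is a single unit. Hidden widths start at
`initial_width` and halve per subsequent layer (floor 8); the published
best dense architecture (two 64-unit layers, 13% dropout, L2 1.1e−4) is a
constructible configuration. The LSTM reads the feature vector as eight
zero-padded chunks through forward and backward passes whose final hidden
states feed the dense head. The connectome CNN applies 0–2 edge-to-edge
blocks (row + column rank-2 filters), an edge-to-node and a node-to-graph
layer with leaky-ReLU activations, and appends the covariates at the
graph-level vector.

The experiment engine freezes one stratified split plan — 80/20
train/test and k = 3 CV folds, stratified jointly by diagnosis and sex
(strata too small for k collapse to diagnosis-only with a warning; fold
sizes differ by at most one) — and consumes it for every family; its
checksum is recorded in every search record. Per (family × feature set),
`n_configs` configurations (50 in the full protocol; scaled runs use
fewer) are drawn, each scored by mean validation AUROC over the three
folds; the best (ties to the smaller draw index) is refit on the full
training set and evaluated once on the held-out test set. AUROC is
computed by midranks (ties count one half) and matches exhaustive pair
counting to 1e−12. Search records stream to an append-only JSON-lines
journal so interrupted runs resume without retraining.

The landscape analysis compares kernel density estimates of the top-20%
and bottom-20% records (each ⌈0.2·n⌉ records) over chosen hyperparameter
dimensions — 1-D via `stats::density`, 2-D via `MASS::kde2d`, Scott-style
normal-reference bandwidths, log10 scale for log-drawn dimensions.
Bandwidths are floored at a fraction of the search range so a quantile
set concentrated on a single (integer) value still yields a grid-resolvable
peak; peaks within 5% of a bound are flagged as boundary peaks.

# Importance, null calibration and consensus

The importance of feature j for a trained model is I_j = AUROC_b −
AUROC_a: the drop when column j alone is permuted across subjects,
averaged over 64 independent permutations, computed on the held-out test
rows by default (the information-ablation reading; configurable).
Permutation streams are keyed by feature *name*, so a feature's
repetition values are invariant to which other features are analyzed and
to column order. z-scores are computed across features from the means
(mean 0, sd 1 by construction).

The null distribution refits the same configuration on label-permuted
training data (20 permutations by default; at least 80% must succeed) and
runs the identical PFI, pooling the per-feature mean importances.
Significance is a one-tailed t-test in prediction form: under the null
the observed mean importance is one more draw from the null population,
so t = (I_j − mean(null)) / (sd(null)·√(1 + 1/n₀)) with n₀ − 1 degrees of
freedom. This was a genuinely open design point: testing the 64
repetition values directly against the null looks natural but is badly
anti-conservative, because the repetitions within one feature share the
model and evaluation rows and are strongly correlated — their naive
standard error (sd/8) ignores the between-feature spread of chance
importances, and in calibration runs it declared ~30% of null features
significant at BY 1%. The prediction-form test uses the null sample's own
spread and is calibrated (≈0–1% declared on null cohorts). P-values are
BY-adjusted (the dependence-robust step-up with the harmonic-sum factor);
features with q ≤ 1% are significant; zero-variance repetition samples
get p = 1 and a degenerate flag.

Consensus ranking takes the top five configurations of a cell by mean CV
AUROC, computes each model's z-scored importances, and ranks features by
the median z across models; a feature earns a star when all five models
give z ≥ 3 and a diamond when four of five do. Each consensus feature
also carries a univariate direction mark from a Welch two-sample
two-tailed t-test between diagnostic groups ("+"/"−" at p ≤ 0.05, "o"
otherwise).

# External validation

Source-trained models are applied to an external cohort without
adaptation, using the frozen source artifacts (leakage guard above).
Supervised domain adaptation follows a ten-decile scheme: fold i
fine-tunes on decile i (10%) and tests on the remaining 90%, so every
subject appears in exactly nine test sets. Neural families warm-start
from their trained weights with a reduced learning rate (1e−4) and early
stopping on a stratified 20% sliver of the tuning slice (patience 10,
best state restored — the published protocol names early stopping but no
criterion); zero epochs is an exact no-op whose per-fold AUROC equals the
transfer AUROC. Classical families have no warm start and are refit from
scratch on the tuning slice, flagged `refit` so the two modes are never
conflated. The tuning split is stratified by diagnosis only (site
stratification was left open; diagnosis stratification is the minimal
guarantee that every slice is trainable).

Pre/post-adaptation concordance restricts to features with z > 3 in
either set (union by default — the published rule does not say; the
intersection variant is available) and reports Pearson and Spearman
correlations of mean importances, undefined (flagged) below three
features.

# The synthetic generator

Cohorts emulate the structure of multi-site case–control imaging studies:
a near-balanced binary diagnosis (exactly round(prevalence·n) cases), a
binary sex covariate, and sites acting through two mechanisms — additive
shifts on anatomical features and per-ROI multiplicative variance gains
on the timeseries (the D·Σ·D form leaves correlations intact but shifts
covariance-based features, mimicking channel-wise scanner gain).
Group-level correlation targets follow a block (network) design:
contiguous ROI blocks (~√R networks) with within-block correlation
`base_corr`, planted edges shifted by `delta_corr` in the case group, and
a nearest-correlation projection if a shift breaks positive definiteness
(shifts implying |r| ≥ 1 are rejected naming the edge).

Each subject's correlation matrix is additionally jittered by a zero-mean
symmetric perturbation (`subject_corr_sd`, default 0.3), scaled back per
subject just enough to stay positive definite via a min-eigenvalue
concavity bound. This individual connectivity variability is essential
realism: without it, a handful of planted edges separates the groups
perfectly, every model saturates at AUROC 1.0, and single-feature
ablation has exactly zero effect — permutation importance degenerates.
The default is anchored to the performance regime reported for real
case–control connectome studies (AUROC around 0.8–0.9 for strong
signals), not to any test threshold. Timeseries are zero-mean
multivariate normal; the normal model, like everything else about the
data distribution, is the generator's own assumption — real fMRI
autocorrelation, motion artifacts and hemodynamics are out of scope, so
passing tests certify the statistical machinery, not fMRI realism.

One master seed fans out through hashed substreams (per subject, per
feature, per stage), so cohorts are bit-reproducible and extensible.
External cohorts share the planted signal but draw their own site
effects, demographics and seed; a no-op shift with the same seed
reproduces the source cohort exactly.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which the verified properties are statistically
meaningful: tangent-geometry oracles at R ≤ 10; search bookkeeping on
cohorts of 60–160 subjects; type-I calibration on ten null cohorts of
n = 200, R = 16 (120 edges) with the full 64-repetition, 20-permutation
pipeline; biomarker recovery on n = 400, R = 16, T = 200 with five
planted edges at delta 0.3 and a ten-configuration dense-network search;
transfer/adaptation on n = 200 cohorts over five seeded replicates.
Degenerate inputs are handled explicitly: constant ROIs error by name,
constant features are flagged and zeroed, degenerate importance samples
get p = 1, landscape quantiles with identical performance raise a
degenerate flag, and adaptation folds missing a class are skipped and
logged.

# Known limitations

Covariance→tangent is the only connectivity representation (no
full/partial correlation variants); no nested CV; no ensembling; no
Bayesian/hyperband search; no unsupervised or adversarial adaptation; no
site harmonization; no atlas geometry or brain-space rendering. The
neural engine is CPU-oriented and deliberately compact — at the scales
above it trains in seconds, but it is not a GPU framework.
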