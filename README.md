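# conndiag

Diagnostic modelling and reproducible-biomarker discovery from brain
connectomes, for researchers who classify case vs control from
resting-state functional connectivity (plus anatomical features) and want
to know *which connections* the models agree on — and whether those
findings survive an external cohort.

The motivating application is autism-spectrum-disorder (ASD) vs typically
developing (TD) classification from ROI-timeseries connectivity. Since
that requires large imaging datasets, the package ships a first-class
synthetic-cohort generator with planted ground truth (group differences
on known edges, multi-site batch effects, demographic shifts), so the
entire pipeline is testable on a laptop.

## What is inside

- **Tangent-space connectivity features.** Subject covariances C_i
  (Ledoit–Wolf-style shrinkage) are embedded at the training population's
  Riemannian geometric mean G: the features are the strict upper triangle
  of logm(G^(-1/2) C_i G^(-1/2)). The reference and the feature scaler
  are frozen, checksummed artifacts — external cohorts are never allowed
  to refit them.
- **A 12-family model zoo** (3 classical linear, 6 classical nonlinear,
  3 neural: dense feedforward, bidirectional LSTM, edge-to-edge
  connectome CNN) behind one `fit_model()` / `predict_score()` contract,
  each with its published hyperparameter search space stored as data.
- **An unbiased search protocol**: one frozen stratified 80/20 split with
  3-fold CV consumed by every family, random configuration draws,
  selection by mean validation AUROC, one held-out test evaluation, and a
  KDE landscape contrasting top- vs bottom-quintile configurations.
- **Biomarker discovery**: permutation feature importance
  I = AUROC_before − AUROC_after over 64 permutations per feature, a
  label-permutation null, one-tailed t significance with
  Benjamini–Yekutieli FDR at 1%, consensus ranking by median z across the
  top-5 models (star: all five z ≥ 3; diamond: four of five), and
  univariate direction marks (+/−/o by Welch t-test).
- **External validation**: transfer without adaptation under a leakage
  guard, ten-fold supervised domain adaptation (fine-tune on 10%, test on
  90%), and pre/post-adaptation importance concordance (Pearson and
  Spearman over significant edges).

## A worked example

```r
library(conndiag)

spec <- cohort_spec(n_subjects = 160, n_rois = 10, n_timepoints = 120,
                    n_anat = 6,
                    planted_edges = list(c(1, 2, 0.35), c(3, 7, 0.35)),
                    seed = 42)
cohort <- generate_cohort(spec)
cohort
#> Synthetic connectome cohort: 160 subjects (80 case / 80 control), 10 ROIs x 120 timepoints, 6 anatomical features, 3 sites
#>   planted edges: 2; planted anat effects: 0

plan <- make_split_plan(cohort_labels(cohort), cohort_sex(cohort), seed = 1)
search <- run_search(cohort, families = c("logistic_ridge", "dfnn"),
                     feature_sets = "functional", n_configs = 5,
                     plan = plan, seed = 2)
search
#> Hyperparameter search: 2 families x 1 feature sets x 5 configs (10 records)
#> Held-out test AUROC:
#>                functional
#> logistic_ridge      0.973
#> dfnn                0.977

ir <- interrogate_cell(search, cohort, "dfnn", "functional", top_m = 3,
                       top_k = 5, n_reps = 32, seed = 3, with_null = FALSE)
ir$consensus[, c("feature", "median_z", "n_above", "star", "direction")]
#>    feature    median_z n_above  star direction
#> 1 edge_1_2  5.25072721       3  TRUE         +
#> 2 edge_3_7  3.58370352       3  TRUE         +
#> 3 edge_4_8  0.04348307       0 FALSE         o
#> 4 edge_5_6 -0.02815939       0 FALSE         -
#> 5 edge_7_9 -0.06694802       0 FALSE         o
```

Both planted edges (1–2 and 3–7) head the consensus list with z-scored
importance above 3 in every interrogated model (star) and are marked "+"
— their connectivity is higher in the case group, which is how they were
planted. The remaining edges sit at chance.

`run_pipeline(run_config(...))` orchestrates the stages end-to-end into
an output directory (split plan, search journal, result matrix,
importance and consensus tables, transfer report, manifest), and
`inst/cli/conndiag.R` is a thin command-line wrapper over the same
functions.

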