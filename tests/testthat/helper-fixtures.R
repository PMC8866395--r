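# Shared fixtures: all data is generated in code at test time.

# random SPD matrix with eigenvalues bounded away from zero
random_spd <- function(R, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(R * R), R, R)
  crossprod(A) / R + diag(0.5, R)
}

# eigendecomposition-based matrix-log oracle (independent of tangent_embed:
# forms the whitened matrix explicitly via solve() and an eigen log)
logm_oracle <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% diag(log(e$values), nrow(M)) %*% t(e$vectors)
}

# small cohort with two strongly planted edges, for model-level tests
small_signal_cohort <- function(n = 80, R = 8, T_ = 80, seed = 5) {
  generate_cohort(cohort_spec(
    n, R, T_, n_anat = 5,
    planted_edges = list(c(1, 2, 0.4), c(3, min(5, R), 0.4)),
    seed = seed))
}

# standardized features + labels for a cohort, with kinds attribute set
features_with_kinds <- function(cohort, mode = "functional",
                                fit_idx = seq_along(cohort$subjects)) {
  fb <- build_features(cohort, mode, fit_idx = fit_idx)
  X <- fb$X
  attr(X, "kinds") <- fb$kinds
  list(X = X, y = cohort_labels(cohort), fb = fb)
}

# fixed small configurations so classical/neural fits stay fast
tiny_config <- function(family) {
  vals <- switch(family,
    naive_bayes = list(),
    random_forest = list(estimators = 80L, max_nodes = 16L),
    extra_trees = list(estimators = 80L, max_nodes = 16L),
    adaboost = list(estimators = 40L, learning_rate = 1),
    gradient_boosting = list(estimators = 40L, learn_rate = 0.3,
                             max_depth = 3L, subsample = 0.8,
                             colsample = 0.8),
    svm_gaussian = list(C = 1, max_iter = 1e4, gamma = 0.02),
    svm_linear = list(C = 1, max_iter = 1e4),
    logistic_lasso = list(C = 1, max_iter = 1e5),
    logistic_ridge = list(C = 1, max_iter = 1e5),
    dfnn = list(hidden_layers = 1L, initial_width = 24L, dropout = 0.15,
                l2 = 1e-3),
    lstm = list(hidden_layers = 1L, initial_width = 16L, dropout = 0.15,
                l2 = 1e-3),
    brainnet_cnn = list(hidden_layers = 1L, initial_width = 8L,
                        dropout = 0.15, leaky_slope = 0.3))
  structure(list(family = family, values = vals, draw_index = 1L,
                 seed = 1L), class = "model_config")
}

# brute-force Benjamini-Yekutieli step-up oracle
by_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- m * cm * p[o] / seq_len(m)
  # step-up: enforce monotonicity from the largest rank down
  adj <- rev(cummin(rev(adj)))
  q <- numeric(m)
  q[o] <- pmin(adj, 1)
  q
}

# exhaustive concordant-pair AUROC oracle (ties count one half)
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}
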