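# Model zoo: registry completeness, configuration sampling, the
# fit/score contract across all twelve families.

test_that("the zoo has twelve families in a 3/6/3 category split", {
  fams <- model_families()
  expect_equal(nrow(fams), 12)
  expect_equal(sum(fams$category == "linear"), 3)
  expect_equal(sum(fams$category == "nonlinear"), 6)
  expect_equal(sum(fams$category == "deep"), 3)
  expect_equal(fams$family[fams$square_input], "brainnet_cnn")
})

test_that("config sampling respects bounds, scales and determinism", {
  for (fam in model_families()$family) {
    space <- hyperparameter_space(fam)
    for (i in 1:25) {
      cfg <- sample_config(fam, seed = i)
      for (d in names(space)) {
        expect_gte(cfg$values[[d]], space[[d]]$lo)
        expect_lte(cfg$values[[d]], space[[d]]$hi)
        if (identical(space[[d]]$type, "integer"))
          expect_true(cfg$values[[d]] == round(cfg$values[[d]]))
      }
    }
    expect_identical(sample_config(fam, seed = 5), sample_config(fam, seed = 5))
  }
  # log-uniform draws of C land roughly evenly across its nine decades
  C <- vapply(1:4500, function(i) sample_config("svm_linear", seed = i)$values$C, 0)
  frac <- table(factor(floor(log10(C)), levels = -4:4)) / length(C)
  expect_true(all(abs(frac - 1 / 9) < 0.02))
  # the printed adaptive-boosting range is kept, with a conventional
  # alternative behind a flag
  expect_equal(hyperparameter_space("adaboost")$learning_rate$lo, 5)
  alt <- hyperparameter_space("adaboost", adaboost_conventional_lr = TRUE)
  expect_lte(alt$learning_rate$hi, 1)
})

test_that("every family fits, scores, and reproduces itself from seed", {
  coh <- small_signal_cohort(n = 80, R = 8, T_ = 80)
  fw <- features_with_kinds(coh, fit_idx = 1:60)
  Xtr <- fw$X[1:60, ]; attr(Xtr, "kinds") <- attr(fw$X, "kinds")
  Xte <- fw$X[61:80, ]; attr(Xte, "kinds") <- attr(fw$X, "kinds")
  ytr <- fw$y[1:60]; yte <- fw$y[61:80]
  aurocs <- c()
  for (fam in model_families()$family) {
    m <- fit_model(fam, tiny_config(fam), Xtr, ytr, seed = 11)
    s <- predict_score(m, Xte)
    expect_length(s, 20)
    m2 <- fit_model(fam, tiny_config(fam), Xtr, ytr, seed = 11)
    expect_identical(s, predict_score(m2, Xte))
    aurocs[fam] <- compute_auroc(s, yte)
  }
  # the planted linear signal is recoverable by every family
  expect_true(all(aurocs > 0.7))
  # no family category is broken relative to the others on linear signal
  fams <- model_families()
  expect_lt(max(aurocs[fams$family[fams$category == "deep"]]) -
              max(aurocs[fams$family[fams$category == "linear"]]), 0.05)
})

test_that("the fit/score contract enforces its preconditions", {
  coh <- small_signal_cohort(n = 40, R = 6, T_ = 40)
  fw <- features_with_kinds(coh)
  X <- fw$X
  # square-input family rejects matrices without edge features
  fa <- build_features(coh, "anatomical")
  Xa <- fa$X; attr(Xa, "kinds") <- fa$kinds
  expect_error(fit_model("brainnet_cnn", tiny_config("brainnet_cnn"),
                         Xa, fw$y, seed = 1),
               "square connectivity")
  # signature mismatch on scoring
  m <- fit_model("logistic_ridge", tiny_config("logistic_ridge"), X,
                 fw$y, seed = 1)
  expect_error(predict_score(m, Xa), "signature")
  # single-class labels rejected
  expect_error(fit_model("logistic_ridge", tiny_config("logistic_ridge"),
                         X, rep(1, nrow(X))), "both classes")
  # separable toy problem is learned perfectly by ridge logistic
  Xs <- cbind(f1 = c(rep(-2, 10), rep(2, 10)), f2 = rnorm(20))
  ys <- rep(c(0, 1), each = 10)
  ms <- fit_model("logistic_ridge",
                  structure(list(family = "logistic_ridge",
                                 values = list(C = 100, max_iter = 1e5),
                                 draw_index = 1L, seed = 1L),
                            class = "model_config"),
                  Xs, ys)
  expect_equal(compute_auroc(predict_score(ms, Xs), ys), 1.0)
})

test_that("the best published dense architecture is constructible", {
  cfg <- structure(list(family = "dfnn",
                        values = list(hidden_layers = 2L,
                                      initial_width = 64L, dropout = 0.13,
                                      l2 = 1.1e-4),
                        draw_index = 1L, seed = 1L),
                   class = "model_config")
  set.seed(3)
  X <- matrix(rnorm(40 * 12), 40, 12,
              dimnames = list(NULL, paste0("f", 1:12)))
  y <- as.integer(X[, 1] > 0)
  m <- fit_model("dfnn", cfg, X, y, seed = 2)
  expect_s3_class(m, "conn_model")
  expect_length(predict_score(m, X), 40)
})

test_that("label-permuted training yields chance-level held-out AUROC", {
  set.seed(14)
  coh <- small_signal_cohort(n = 100, R = 6, T_ = 60)
  fw <- features_with_kinds(coh, fit_idx = 1:70)
  aur <- vapply(1:5, function(s) {
    y_perm <- conndiag:::with_seed(s, sample(fw$y[1:70]))
    m <- fit_model("logistic_ridge", tiny_config("logistic_ridge"),
                   fw$X[1:70, ], y_perm, seed = s)
    compute_auroc(predict_score(m, fw$X[71:100, ]), fw$y[71:100])
  }, 0)
  expect_lt(abs(mean(aur) - 0.5), 0.1)
})
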