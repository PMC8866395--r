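# External validation: frozen-artifact transfer, domain adaptation,
# importance concordance.

test_that("identity transfer reproduces source test AUROCs exactly", {
  coh <- small_signal_cohort(n = 70, R = 6, T_ = 60, seed = 21)
  plan <- make_split_plan(cohort_labels(coh), cohort_sex(coh), seed = 2)
  sr <- run_search(coh, "logistic_ridge", "functional", n_configs = 2,
                   plan = plan, seed = 3)
  best <- sr$best[["logistic_ridge::functional"]]
  # external cohort = the source cohort itself, frozen artifacts
  fe <- external_features(coh, "functional", best$ref, best$scaler,
                          best$site_levels)
  Xe <- fe$X[plan$test, , drop = FALSE]
  tr <- transfer_evaluate(list(best$model), Xe,
                          cohort_labels(coh)[plan$test], best$ref,
                          best$scaler)
  expect_identical(tr$auroc[[1]],
                   sr$result_matrix["logistic_ridge", "functional"])
  # scrambled labels: chance level
  y_scr <- conndiag:::with_seed(4, sample(cohort_labels(coh)[plan$test]))
  tr_scr <- transfer_evaluate(list(best$model), Xe, y_scr)
  expect_lt(abs(tr_scr$auroc[[1]] - 0.5), 0.35)
})

test_that("the leakage guard rejects refit preprocessing artifacts", {
  coh <- small_signal_cohort(n = 50, R = 5, T_ = 40, seed = 22)
  fb <- build_features(coh, "functional", fit_idx = 1:35)
  X <- fb$X; attr(X, "kinds") <- fb$kinds
  m <- fit_model("logistic_ridge", tiny_config("logistic_ridge"),
                 X[1:35, ], cohort_labels(coh)[1:35], seed = 1,
                 artifact_checksums = list(reference = fb$ref$checksum,
                                           scaler = fb$scaler$checksum))
  # refit artifacts on different rows: checksum differs, hard error
  fb2 <- build_features(coh, "functional", fit_idx = 10:45)
  expect_error(transfer_evaluate(list(m), X, cohort_labels(coh),
                                 fb2$ref, fb2$scaler),
               "leakage guard")
  expect_silent(invisible(transfer_evaluate(list(m), X,
                                            cohort_labels(coh),
                                            fb$ref, fb$scaler)))
})

test_that("ten-fold adaptation partitions cover each subject nine times", {
  coh <- small_signal_cohort(n = 100, R = 5, T_ = 40, seed = 23)
  fw <- features_with_kinds(coh, fit_idx = 1:100)
  m <- fit_model("dfnn", tiny_config("dfnn"), fw$X, fw$y, seed = 1)
  ad <- domain_adapt(m, fw$X, fw$y, k = 10, seed = 2, max_epochs = 0)
  folds <- ad$folds
  expect_equal(sort(unique(folds)), 1:10)
  # deciles partition the cohort (sizes 10 each), so every subject sits in
  # exactly one tuning slice and in 9 of the 10 "90%" test sets
  expect_true(all(table(folds) == 10))
  test_appearances <- vapply(seq_len(100), function(s)
    sum(seq_len(10) != folds[s]), 0)
  expect_true(all(test_appearances == 9))
  # zero-epoch adaptation equals transfer on every fold
  expect_equal(ad$tuned_auroc, ad$transfer_auroc, tolerance = 1e-12)
})

test_that("classical families adapt by refit and are flagged as such", {
  coh <- small_signal_cohort(n = 60, R = 5, T_ = 40, seed = 24)
  fw <- features_with_kinds(coh)
  m <- fit_model("logistic_ridge", tiny_config("logistic_ridge"), fw$X,
                 fw$y, seed = 1)
  ad <- domain_adapt(m, fw$X, fw$y, k = 5, seed = 2)
  expect_equal(ad$mode, "refit")
  expect_true(all(is.finite(ad$tuned_auroc)))
})

test_that("importance concordance matches closed-form correlations", {
  mk <- function(mi, z) {
    out <- data.frame(feature = paste0("f", seq_along(mi)),
                      mean_importance = mi, z = z)
    class(out) <- c("conn_importance", "data.frame")
    out
  }
  z_hi <- c(5, 4, 6, 3.5, 4.2, 0, -1)
  mi <- c(0.9, 0.5, 0.7, 0.2, 0.4, 0.01, 0)
  pre <- mk(mi, z_hi)
  # identity: both correlations 1
  cc <- importance_concordance(pre, pre)
  expect_equal(cc$pearson, 1.0)
  expect_equal(cc$spearman, 1.0)
  expect_equal(cc$n, 5)
  # antisymmetry: Pearson -1
  post <- mk(-mi, z_hi)
  expect_equal(importance_concordance(pre, post)$pearson, -1.0)
  # 5-point hand check against the textbook formulas
  a <- c(0.9, 0.5, 0.7, 0.2, 0.4); b <- c(0.8, 0.1, 0.9, 0.3, 0.2)
  post2 <- mk(c(b, 0.0, 0.0), z_hi)
  cc2 <- importance_concordance(pre, post2)
  pearson_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  spearman_hand <- cor(rank(a), rank(b))
  expect_equal(cc2$pearson, pearson_hand, tolerance = 1e-12)
  expect_equal(cc2$spearman, spearman_hand, tolerance = 1e-12)
  # under 3 shared features: undefined, flagged
  few <- mk(c(1, 0.5, 0, 0, 0, 0, 0), c(4, 3.5, 0, 0, 0, 0, 0))
  cc3 <- importance_concordance(few, few)
  expect_true(cc3$undefined)
  expect_true(is.na(cc3$pearson))
})
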