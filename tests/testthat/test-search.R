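# Search protocol: bookkeeping, fairness, selection consistency,
# determinism, journal resume, landscape analysis.

make_search_fixture <- function(n_configs = 3, families =
                                  c("logistic_ridge", "naive_bayes"),
                                feature_sets = "functional", seed = 3,
                                journal = NULL) {
  coh <- small_signal_cohort(n = 70, R = 6, T_ = 60, seed = 12)
  plan <- make_split_plan(cohort_labels(coh), cohort_sex(coh), seed = 2)
  list(cohort = coh, plan = plan,
       search = run_search(coh, families, feature_sets,
                           n_configs = n_configs, plan = plan,
                           seed = seed, journal = journal))
}

test_that("search bookkeeping matches the experiment arithmetic", {
  fx <- make_search_fixture(n_configs = 3,
                            feature_sets = c("functional", "anatomical"))
  df <- search_records(fx$search)
  expect_equal(nrow(df), 2 * 2 * 3)
  expect_equal(dim(fx$search$result_matrix), c(2, 2))
  expect_true(all(is.finite(fx$search$result_matrix)))
  expect_equal(sum(df$selected), 4)
  # every validation AUROC within [0, 1], 3 folds per record
  expect_true(all(vapply(fx$search$records, function(r)
    length(r$fold_auroc) == 3 && all(r$fold_auroc >= 0 & r$fold_auroc <= 1),
    TRUE)))
})

test_that("one frozen plan is consumed by every family (fairness)", {
  fx <- make_search_fixture()
  df <- search_records(fx$search)
  expect_equal(unique(df$plan_checksum), fx$plan$checksum)
  # selection consistency: the selected config has the maximal mean CV
  # AUROC of its cell, with ties to the smaller index
  for (cell in split(df, paste(df$family, df$feature_set))) {
    best <- cell[cell$selected, ]
    expect_equal(best$mean_cv_auroc, max(cell$mean_cv_auroc))
    expect_equal(best$config_index,
                 min(cell$config_index[cell$mean_cv_auroc ==
                                         max(cell$mean_cv_auroc)]))
  }
})

test_that("the full search is bit-deterministic under one master seed", {
  fx1 <- make_search_fixture(seed = 7)
  fx2 <- make_search_fixture(seed = 7)
  expect_identical(fx1$search$result_matrix, fx2$search$result_matrix)
  expect_identical(search_records(fx1$search), search_records(fx2$search))
})

test_that("an interrupted search resumes from its journal unchanged", {
  j1 <- tempfile(fileext = ".jsonl")
  fx_full <- make_search_fixture(seed = 5, journal = j1)
  # simulate an interruption: keep only the first half of the journal
  lines <- readLines(j1)
  j2 <- tempfile(fileext = ".jsonl")
  writeLines(lines[seq_len(floor(length(lines) / 2))], j2)
  coh <- fx_full$cohort
  resumed <- run_search(coh, c("logistic_ridge", "naive_bayes"),
                        "functional", n_configs = 3, plan = fx_full$plan,
                        seed = 5, journal = j2)
  expect_equal(resumed$result_matrix, fx_full$search$result_matrix,
               tolerance = 1e-12)
  unlink(c(j1, j2))
})

test_that("a planted-signal search beats chance; square-input cells skip", {
  # the 3-SE chance bound needs a test set large enough for the binomial
  # SE to be informative (20% of 160 = 32 subjects -> bound ~ 0.72)
  coh <- small_signal_cohort(n = 160, R = 6, T_ = 80, seed = 12)
  plan <- make_split_plan(cohort_labels(coh), cohort_sex(coh), seed = 2)
  sr <- run_search(coh, "brainnet_cnn", c("functional", "anatomical"),
                   n_configs = 2, plan = plan, seed = 4)
  expect_true(is.na(sr$result_matrix["brainnet_cnn", "anatomical"]))
  # null AUROC standard error over the test set bounds chance performance
  n1 <- sum(cohort_labels(coh)[plan$test])
  n0 <- length(plan$test) - n1
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_gt(sr$result_matrix["brainnet_cnn", "functional"], 0.5 + 3 * se)
})

test_that("landscape KDE finds a planted optimum away from the boundary", {
  set.seed(44)
  recs <- data.frame(layers = sample(1:5, 300, replace = TRUE))
  recs$mean_cv_auroc <- 0.8 - 0.05 * (recs$layers - 3)^2 +
    rnorm(300, sd = 0.01)
  ls <- landscape_kde(recs, dims = "layers", bounds = list(layers = c(1, 5)))
  expect_equal(ls$n_quantile, ceiling(0.2 * 300))
  expect_lt(abs(ls$top_peak[["layers"]] - 3), 0.5)
  expect_false(ls$top_peak_on_boundary)
  # bottom quantile concentrates at the extremes
  expect_gt(abs(ls$bottom_peak[["layers"]] - 3), 0.75)
  # identical performances: degenerate flag
  recs2 <- data.frame(layers = rep(1:5, 4), mean_cv_auroc = 0.7)
  ls2 <- landscape_kde(recs2, dims = "layers")
  expect_true(ls2$degenerate)
  # two-dimensional landscape with a log-scaled dimension
  recs3 <- data.frame(width = 2^sample(4:8, 300, replace = TRUE),
                      layers = sample(1:5, 300, replace = TRUE))
  recs3$mean_cv_auroc <- 0.8 - 0.03 * (log2(recs3$width) - 6)^2 -
    0.03 * (recs3$layers - 3)^2 + rnorm(300, sd = 0.01)
  ls3 <- landscape_kde(recs3, dims = c("width", "layers"),
                       log_dims = "width",
                       bounds = list(width = c(16, 256),
                                     layers = c(1, 5)))
  expect_lt(abs(log2(ls3$top_peak[["width"]]) - 6), 1.1)
  expect_lt(abs(ls3$top_peak[["layers"]] - 3), 1)
})
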