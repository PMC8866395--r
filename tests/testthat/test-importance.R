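# Permutation feature importance, its null, BY-FDR, consensus ranking
# and direction marks.

ridge_cfg <- function(C = 1) {
  structure(list(family = "logistic_ridge",
                 values = list(C = C, max_iter = 1e5),
                 draw_index = 1L, seed = 1L), class = "model_config")
}

test_that("importance isolates informative features and normalizes z", {
  set.seed(51)
  n <- 120
  # note: across m features the z of a single standout is capped at
  # sqrt(m - 1), so exceeding 3 needs m > 10
  X <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- as.integer(X[, 4] + rnorm(n, sd = 0.4) > 0)
  m <- fit_model("logistic_ridge", ridge_cfg(), X, y, seed = 1)
  imp <- permutation_importance(m, X, y, n_reps = 32, seed = 2)
  expect_equal(dim(attr(imp, "reps")), c(32, 20))
  # z-scores across features: mean 0, sd 1
  expect_lt(abs(sum(imp$z)), 1e-8)
  expect_equal(sd(imp$z), 1, tolerance = 1e-8)
  # the single informative feature dominates
  expect_equal(imp$feature[which.max(imp$z)], "f4")
  expect_gte(max(imp$z), 3 * (1 - 1e-9))
  # a feature with exactly zero coefficient has importance ~ 0
  uninform <- imp$mean_importance[imp$feature != "f4"]
  expect_lt(max(abs(uninform)), 0.05)
})

test_that("importance of a feature is invariant to column order", {
  set.seed(52)
  n <- 80
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.integer(X[, 2] + rnorm(n, sd = 0.5) > 0)
  perm <- c(4, 2, 6, 1, 3, 5)
  Xp <- X[, perm]
  m1 <- fit_model("logistic_ridge", ridge_cfg(), X, y, seed = 3)
  m2 <- fit_model("logistic_ridge", ridge_cfg(), Xp, y, seed = 3)
  i1 <- permutation_importance(m1, X, y, n_reps = 16, seed = 4)
  i2 <- permutation_importance(m2, Xp, y, n_reps = 16, seed = 4)
  # permutation streams are keyed by feature name, so each feature's
  # repetition values agree exactly across orderings
  reo <- match(i1$feature, i2$feature)
  expect_equal(attr(i2, "reps")[, reo], attr(i1, "reps"),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("label-permutation null is centred and seed-stable", {
  set.seed(53)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c(0L, 1L), 30)
  null1 <- build_null("logistic_ridge", ridge_cfg(), X[1:40, ], y[1:40],
                      X[41:60, ], y[41:60], n_label_perms = 6,
                      n_reps = 16, seed = 9)
  null2 <- build_null("logistic_ridge", ridge_cfg(), X[1:40, ], y[1:40],
                      X[41:60, ], y[41:60], n_label_perms = 6,
                      n_reps = 16, seed = 9)
  expect_identical(null1$values, null2$values)
  se <- sd(null1$values) / sqrt(length(null1$values))
  expect_lt(abs(mean(null1$values)), 2 * se + 1e-3)
})

test_that("BY adjustment matches a brute-force step-up oracle", {
  set.seed(54)
  for (i in 1:1000) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(c(1, 2), 1) # mix of null-ish and signal-ish
    expect_equal(p.adjust(p, method = "BY"), by_oracle(p),
                 tolerance = 1e-12)
  }
  # single test: BY reduces to the unadjusted comparison, c(1) = 1
  expect_equal(p.adjust(0.001, method = "BY"), 0.001)
  expect_true(0.001 <= 0.01 * 1 / 1)
})

test_that("significance fills p and q and controls the null", {
  set.seed(55)
  n <- 80
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- as.integer(X[, 1] + rnorm(n, sd = 0.3) > 0)
  m <- fit_model("logistic_ridge", ridge_cfg(), X[1:60, ], y[1:60],
                 seed = 1)
  imp <- permutation_importance(m, X[61:80, ], y[61:80], n_reps = 32,
                                seed = 2)
  null <- build_null("logistic_ridge", ridge_cfg(), X[1:60, ], y[1:60],
                     X[61:80, ], y[61:80], n_label_perms = 8, n_reps = 32,
                     seed = 3)
  res <- significance(imp, null, fdr_rate = 0.01)
  expect_true(all(c("p", "q", "significant") %in% names(res)))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$q >= res$p - 1e-12))
  expect_true(res$significant[res$feature == "f1"])
  # all p = 1 leaves nothing significant
  imp_flat <- imp
  attr(imp_flat, "reps")[] <- 0
  res_flat <- significance(imp_flat, null)
  expect_false(any(res_flat$significant))
  expect_true(all(res_flat$degenerate))
})

test_that("consensus ranking applies the star/diamond flag rules", {
  mk <- function(z) {
    out <- data.frame(feature = paste0("f", seq_along(z)),
                      mean_importance = z / 10, z = z)
    attr(out, "reps") <- matrix(0, 2, length(z))
    class(out) <- c("conn_importance", "data.frame")
    out
  }
  # five identical models: all-or-nothing flags
  zs <- c(5, 4, 2, -1, 0, -2)
  il <- lapply(1:5, function(i) mk(zs))
  cr <- consensus_rank(il, top_k = 3)
  expect_equal(cr$feature, c("f1", "f2", "f3"))
  expect_true(all(cr$star[1:2]))
  expect_false(any(cr$diamond[1:2]))
  expect_false(cr$star[3] || cr$diamond[3])
  # (4,4,4,2,4): no star, diamond
  il2 <- lapply(c(4, 4, 4, 2, 4), function(v) mk(c(v, 0, 0)))
  cr2 <- consensus_rank(il2, top_k = 1)
  expect_false(cr2$star[1])
  expect_true(cr2$diamond[1])
  expect_equal(cr2$median_z[1], 4)
  expect_error(consensus_rank(list(mk(c(1, 2, 3)), mk(c(1, 2)))),
               "namespace")
})

test_that("direction marks follow a hand-computed Welch test", {
  # identical groups: o
  X <- cbind(f1 = rep(c(1, 2, 3, 4), 2))
  y <- rep(c(0, 1), each = 4)
  expect_equal(direction_mark(X, y, "f1")$mark, "o")
  # forced direction: case column higher
  set.seed(56)
  X2 <- cbind(f1 = c(rnorm(50, 0, 0.1), rnorm(50, 1, 0.1)))
  y2 <- rep(c(0, 1), each = 50)
  expect_equal(direction_mark(X2, y2, "f1")$mark, "+")
  expect_equal(direction_mark(-X2, y2, "f1")$mark, "-")
  # 4-vs-4 sample against the closed-form Welch computation
  x1 <- c(1.1, 2.3, 1.9, 2.7); x0 <- c(0.6, 1.2, 0.8, 1.0)
  s1 <- var(x1) / 4; s0 <- var(x0) / 4
  t_hand <- (mean(x1) - mean(x0)) / sqrt(s1 + s0)
  df_hand <- (s1 + s0)^2 / (s1^2 / 3 + s0^2 / 3)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  dm <- direction_mark(cbind(f = c(x0, x1)), rep(c(0, 1), each = 4), "f")
  expect_equal(dm$t, t_hand, tolerance = 1e-12)
  expect_equal(dm$p, p_hand, tolerance = 1e-12)
  expect_equal(dm$mark, if (p_hand <= 0.05) "+" else "o")
})
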