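# Feature assembly and the frozen-preprocessing contracts.

test_that("scaler standardizes fit rows and stays frozen elsewhere", {
  set.seed(21)
  X <- matrix(rnorm(50 * 6, mean = 3, sd = 2), 50, 6)
  colnames(X) <- paste0("f", 1:6)
  sc <- fit_scaler(X, fit_rows = 1:30)
  Z <- apply_scaler(sc, X)
  expect_lt(max(abs(colMeans(Z[1:30, ]))), 1e-10)
  expect_equal(unname(apply(Z[1:30, ], 2, sd)), rep(1, 6),
               tolerance = 1e-10)
  # a shifted external population keeps nonzero means (frozen statistics)
  X_ext <- X + 5
  Z_ext <- apply_scaler(sc, X_ext)
  expect_true(all(abs(colMeans(Z_ext)) > 1))
  # constant column: flagged, zeroed, not divided
  X2 <- cbind(X, fconst = 5)
  sc2 <- fit_scaler(X2)
  expect_true(sc2$constant["fconst"])
  expect_true(all(apply_scaler(sc2, X2)[, "fconst"] == 0))
})

test_that("feature-set assembly follows the concatenation contract", {
  n <- 10
  edges <- matrix(rnorm(n * 45), n, 45,
                  dimnames = list(NULL, paste0("e", 1:45)))
  anat <- matrix(rnorm(n * 20), n, 20)
  sex <- rep(c(0, 1), 5)
  site <- rep(1:3, length.out = n)
  comb <- assemble_feature_set("combined", edges, anat, sex, site)
  expect_equal(ncol(comb), 45 + 20 + 1 + 3)
  expect_equal(attr(comb, "kinds"),
               c(rep("functional", 45), rep("anatomical", 20),
                 rep("covariate", 4)))
  # anatomical mode ignores edges even if supplied
  an_only <- assemble_feature_set("anatomical", edges, anat, sex, site)
  expect_equal(ncol(an_only), 20 + 4)
  expect_false(any(grepl("^e", colnames(an_only))))
  fun_only <- assemble_feature_set("functional", edges, NULL, sex, site)
  expect_equal(ncol(fun_only), 45 + 4)
  # R = 64 worth of edges gives the published edge-feature count
  expect_equal(64 * 63 / 2, 2016)
  # unseen site maps to all-zero one-hot with a warning
  expect_warning(
    oh <- assemble_feature_set("functional", edges, NULL, sex,
                               site = c(rep(1, 9), 9),
                               site_levels = 1:3),
    "all-zero")
  expect_equal(unname(oh[10, c("cov_site_1", "cov_site_2", "cov_site_3")]),
               c(0, 0, 0))
})

test_that("external features reuse the source reference and scaler", {
  coh <- small_signal_cohort(n = 30, R = 5, T_ = 40)
  fb <- build_features(coh, "functional", fit_idx = 1:20)
  ext <- generate_external_cohort(coh$spec, site_effect_sd = 0.6,
                                  seed = 77)
  fe <- external_features(ext, "functional", fb$ref, fb$scaler,
                          fb$site_levels)
  # nothing was refit: checksums carried through
  expect_identical(fe$ref$checksum, fb$ref$checksum)
  expect_identical(fe$scaler$checksum, fb$scaler$checksum)
  expect_identical(attr(fe$X, "reference_checksum"), fb$ref$checksum)
})

test_that("reference and scaler serialize through JSON faithfully", {
  mats <- lapply(1:3, function(i) random_spd(4, seed = i))
  ref <- tangent_reference(mats)
  f <- tempfile(fileext = ".json")
  write_tangent_reference(ref, f)
  ref2 <- read_tangent_reference(f)
  expect_equal(ref2$mean, unclass(ref$mean)[, ], tolerance = 1e-12)
  expect_equal(ref2$whitener, ref$whitener, tolerance = 1e-12)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  sc <- fit_scaler(X)
  f2 <- tempfile(fileext = ".json")
  write_scaler(sc, f2)
  sc2 <- read_scaler(f2)
  expect_equal(sc2$mean, sc$mean, tolerance = 1e-12)
  expect_equal(apply_scaler(sc2, X), apply_scaler(sc, X),
               tolerance = 1e-12, ignore_attr = TRUE)
  unlink(c(f, f2))
})
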