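# Synthetic-cohort generator: determinism, exact label counts, planted
# effect calibration, site-effect mechanics, serialization.

test_that("cohorts are reproducible and exactly balanced", {
  spec <- cohort_spec(100, 8, 50, prevalence = 0.5, seed = 42)
  coh <- generate_cohort(spec)
  expect_identical(coh, generate_cohort(spec))
  expect_equal(sum(cohort_labels(coh)), 50)
  # odd count rounds deterministically
  spec2 <- cohort_spec(101, 8, 50, prevalence = 0.46, seed = 42)
  expect_equal(sum(cohort_labels(generate_cohort(spec2))),
               round(0.46 * 101))
  # every timeseries has variance in every ROI
  v <- sapply(coh$subjects, function(s) min(apply(s$timeseries, 2, sd)))
  expect_true(all(v > 0))
})

test_that("group correlation targets are positive definite, bad edges rejected", {
  spec <- cohort_spec(10, 6, 30, planted_edges = list(c(1, 2, 0.4)),
                      base_corr = 0.3, seed = 1)
  coh <- generate_cohort(spec)
  expect_silent(chol(coh$ground_truth$case_correlation))
  expect_silent(chol(coh$ground_truth$control_correlation))
  # planted shift beyond the unit interval names the offending edge
  bad <- cohort_spec(10, 6, 30, planted_edges = list(c(1, 2, 0.8)),
                     base_corr = 0.3, seed = 1)
  expect_error(generate_cohort(bad), "\\(1,2\\)")
})

test_that("a planted edge shifts the empirical correlation by its delta", {
  # Monte-Carlo oracle: average sample correlation difference across many
  # subjects approximates the planted population difference
  spec <- cohort_spec(400, 6, 200, planted_edges = list(c(1, 2, 0.3)),
                      site_effect_sd = 0, seed = 7)
  coh <- generate_cohort(spec)
  y <- cohort_labels(coh)
  r12 <- sapply(coh$subjects, function(s)
    cor(s$timeseries[, 1], s$timeseries[, 2]))
  diff <- mean(r12[y == 1]) - mean(r12[y == 0])
  expect_lt(abs(diff - 0.3), 0.05)
})

test_that("null cohorts produce nominal edge-level rejection rates", {
  spec <- cohort_spec(200, 10, 100, site_effect_sd = 0, seed = 13)
  coh <- generate_cohort(spec)
  y <- cohort_labels(coh)
  pairs <- which(upper.tri(diag(10)), arr.ind = TRUE)
  p <- apply(pairs, 1, function(ij) {
    r <- sapply(coh$subjects, function(s)
      cor(s$timeseries[, ij[1]], s$timeseries[, ij[2]]))
    t.test(r[y == 1], r[y == 0])$p.value
  })
  # 45 edges: at alpha = 0.05 expect about 2 rejections, allow sampling slack
  expect_lte(mean(p < 0.05), 0.15)
})

test_that("external cohorts share signal but shift demographics and sites", {
  spec <- cohort_spec(60, 6, 40, planted_edges = list(c(1, 2, 0.3)),
                      sex_ratio = 0.5, seed = 3)
  # identity shift with the same seed reproduces the cohort
  expect_identical(generate_cohort(spec), generate_external_cohort(spec))
  ext <- generate_external_cohort(spec, sex_ratio = 0.8, seed = 99)
  expect_equal(sum(cohort_sex(ext)), round(0.8 * 60))
  expect_identical(ext$ground_truth$planted_edges, spec$planted_edges)
  # doubling site_effect_sd scales between-site anat variance about 4x
  var_between <- function(sd_site, seeds) {
    mean(sapply(seeds, function(s) {
      co <- generate_cohort(cohort_spec(90, 4, 30, n_anat = 6, n_sites = 3,
                                        site_effect_sd = sd_site, seed = s))
      an <- do.call(rbind, lapply(co$subjects, `[[`, "anat"))
      site <- cohort_site(co)
      mean(apply(an, 2, function(col) var(tapply(col, site, mean))))
    }))
  }
  v1 <- var_between(0.25, 1:8)
  v2 <- var_between(0.5, 1:8)
  expect_gt(v2 / v1, 2)
  expect_lt(v2 / v1, 8)
})

test_that("cohorts round-trip through the plain-text directory layout", {
  coh <- small_signal_cohort(n = 12, R = 4, T_ = 20)
  dir <- tempfile("cohdir_")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(cohort_labels(back), cohort_labels(coh))
  expect_equal(back$subjects[[3]]$timeseries, coh$subjects[[3]]$timeseries,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$subjects[[5]]$anat, coh$subjects[[5]]$anat,
               tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
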