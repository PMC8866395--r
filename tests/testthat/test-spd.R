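# Tangent-space geometry: covariance estimation, Riemannian geometric
# mean, matrix-log embedding, vectorization.

test_that("covariance estimator handles shrinkage limits and symmetry", {
  set.seed(11)
  ts <- matrix(rnorm(60 * 5), 60, 5)
  S_emp <- cov(ts)
  expect_equal(estimate_covariance(ts, shrinkage = 1),
               diag(diag(S_emp), 5), tolerance = 1e-12)
  C <- estimate_covariance(ts)
  expect_lt(max(abs(C - t(C))), 1e-12)
  expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)
  # long iid unit-variance series: off-diagonals near zero
  ts_big <- matrix(rnorm(10000 * 5), 10000, 5)
  C_big <- estimate_covariance(ts_big, shrinkage = 0)
  off <- C_big[upper.tri(C_big)]
  expect_lt(max(abs(off)), 0.05)
  # constant column is rejected by name
  ts_bad <- cbind(ts, 3)
  expect_error(estimate_covariance(ts_bad), "ROI 6")
})

test_that("geometric mean satisfies closed forms and the fixed point", {
  # commuting case: elementwise geometric mean
  G <- spd_geometric_mean(list(diag(c(1, 4)), diag(c(4, 1))))
  expect_equal(unclass(G)[1:2, 1:2], diag(2, 2), tolerance = 1e-10)
  # singleton and idempotence
  C <- random_spd(4, seed = 1)
  expect_equal(unclass(spd_geometric_mean(list(C)))[, ], C,
               tolerance = 1e-12)
  G3 <- spd_geometric_mean(list(C, C, C))
  expect_equal(unclass(G3)[, ], C, tolerance = 1e-6)
  # fixed-point residual at convergence
  set.seed(2)
  mats <- lapply(1:6, function(i) random_spd(5))
  G <- spd_geometric_mean(mats, tol = 1e-7)
  expect_lte(attr(G, "residual"), 1e-7)
  # affine invariance: mean of {A C A'} is A G A'
  A <- matrix(rnorm(25), 5, 5) + diag(2, 5)
  G_t <- spd_geometric_mean(lapply(mats, function(C) A %*% C %*% t(A)))
  expect_equal(unclass(G_t)[, ], A %*% unclass(G)[, ] %*% t(A),
               tolerance = 1e-6)
})

test_that("tangent embedding matches the eigen-log oracle and inverts", {
  set.seed(3)
  for (rep in 1:20) {
    R <- sample(2:10, 1)
    mats <- lapply(1:4, function(i) random_spd(R))
    ref <- tangent_reference(mats)
    C <- random_spd(R)
    emb <- tangent_embed(C, ref)
    W <- ref$whitener
    expect_lt(max(abs(emb - logm_oracle(W %*% C %*% W))), 1e-8)
    # log at the reference point is zero
    expect_lt(max(abs(tangent_embed(ref$mean, ref))), 1e-8)
    # exp/unwhiten inverts the embedding
    Ginvhalf_inv <- solve(W)
    back <- Ginvhalf_inv %*% conndiag:::spd_expm(emb) %*% Ginvhalf_inv
    expect_lt(max(abs(back - C)), 1e-8)
  }
  # diagonal closed form at identity reference
  ref_id <- tangent_reference(list(diag(2)))
  emb <- tangent_embed(diag(c(exp(1), exp(2))), ref_id)
  expect_equal(emb, diag(c(1, 2)), tolerance = 1e-10)
})

test_that("embedding all subjects at their own geometric mean centres", {
  set.seed(4)
  mats <- lapply(1:8, function(i) random_spd(4))
  ref <- tangent_reference(mats)
  embs <- lapply(mats, tangent_embed, ref = ref)
  expect_lt(max(abs(Reduce(`+`, embs) / length(embs))), 1e-6)
})

test_that("upper-triangle vectorization follows the row-major contract", {
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[2, 1] <- 10
  M[1, 3] <- M[3, 1] <- 20
  M[2, 3] <- M[3, 2] <- 30
  v <- vectorize_upper(M)
  expect_equal(unname(v), c(10, 20, 30))
  expect_equal(names(v), c("edge_1_2", "edge_1_3", "edge_2_3"))
  expect_length(vectorize_upper(diag(122) * 0), 7381)
  expect_length(vectorize_upper(diag(64) * 0), 2016)
  expect_error(vectorize_upper(matrix(1:9, 3, 3)), "symmetric")
})
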