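# Symmetric-matrix functional calculus and the affine-invariant geometric
# mean: the geometry underlying tangent-space embedding of connectivity
# matrices.

sym_check <- function(M, tol = 1e-8, what = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(what, " must be a square matrix")
  if (max(abs(M - t(M))) > tol)
    stop(what, " is not symmetric (max asymmetry ",
         format(max(abs(M - t(M)))), ")")
  (M + t(M)) / 2
}

# f applied to the spectrum of a symmetric matrix
sym_fun <- function(M, f, what = "matrix") {
  M <- sym_check(M, what = what)
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

spd_logm <- function(M) {
  e <- eigen(sym_check(M), symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("matrix log requires a positive-definite input (min eigenvalue ",
         format(min(e$values)), ")")
  e$vectors %*% (log(e$values) * t(e$vectors))
}

spd_expm <- function(M) sym_fun(M, exp)

spd_sqrtm <- function(M, inverse = FALSE) {
  e <- eigen(sym_check(M), symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("matrix square root requires a positive-definite input")
  v <- if (inverse) 1 / sqrt(e$values) else sqrt(e$values)
  e$vectors %*% (v * t(e$vectors))
}

is_spd <- function(M, tol = 1e-10) {
  is.matrix(M) && nrow(M) == ncol(M) &&
    max(abs(M - t(M))) <= 1e-8 &&
    min(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values) > tol
}

#' Shrinkage covariance estimate of a multivariate timeseries
#'
#' Estimates the R x R covariance of a T x R ROI-timeseries matrix, blending
#' the empirical covariance toward its diagonal. With `shrinkage = NULL`
#' (default) the shrinkage intensity is chosen analytically in the
#' Ledoit-Wolf style (diagonal target), which keeps the estimate positive
#' definite even when T < R.
#'
#' @param ts numeric matrix, T timepoints x R ROIs
#' @param shrinkage either NULL (analytic) or a fixed fraction in [0,1];
#'   1 returns exactly the diagonal of the empirical covariance
#' @return a symmetric positive-definite R x R matrix
#' @export
estimate_covariance <- function(ts, shrinkage = NULL) {
  if (!is.matrix(ts)) ts <- as.matrix(ts)
  Tn <- nrow(ts); R <- ncol(ts)
  if (Tn < 2) stop("need at least 2 timepoints")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    stop("ROI ", bad, " has a constant timeseries (zero variance)")
  }
  Xc <- sweep(ts, 2, colMeans(ts))
  S <- crossprod(Xc) / (Tn - 1)
  if (is.null(shrinkage)) {
    # analytic intensity for a diagonal target:
    # lambda = sum_{i != j} Var-hat(s_ij) / sum_{i != j} s_ij^2
    W <- array(0, c(R, R))
    num <- 0
    # Var-hat(s_ij) ~ (T/(T-1)^3) * sum_t (x_ti x_tj - mean)^2
    XX <- Xc
    M2 <- crossprod(XX^2) # sum_t x_ti^2 x_tj^2
    SS <- crossprod(XX) / Tn
    varS <- (Tn / (Tn - 1)^3) * (M2 - Tn * SS^2)
    off <- upper_pairs(R)
    num <- 2 * sum(varS[off])
    den <- 2 * sum(S[off]^2)
    lambda <- if (den > 0) min(1, max(0, num / den)) else 1
  } else {
    stopifnot(shrinkage >= 0, shrinkage <= 1)
    lambda <- shrinkage
  }
  Sig <- (1 - lambda) * S + lambda * diag(diag(S), R)
  Sig <- (Sig + t(Sig)) / 2
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    # rank-deficient with zero shrinkage: nudge with a minimal diagonal load
    eps <- abs(min(ev)) + 1e-10 * max(ev)
    Sig <- Sig + diag(eps, R)
  }
  Sig
}

#' Riemannian (affine-invariant) geometric mean of SPD matrices
#'
#' Computes the Frechet mean G of a set of SPD matrices under the
#' affine-invariant metric by the standard fixed-point iteration
#' G <- G^{1/2} expm( mean_i logm(G^{-1/2} C_i G^{-1/2}) ) G^{1/2},
#' with step halving when the residual increases. Convergence is declared
#' when the Frobenius norm of the mean whitened log falls below `tol`.
#'
#' @param mats list of SPD matrices of identical dimension
#' @param tol convergence tolerance on the fixed-point residual
#' @param max_iter maximum iterations
#' @return an SPD matrix with attributes `iterations` and `residual`
#' @export
spd_geometric_mean <- function(mats, tol = 1e-7, max_iter = 200) {
  stopifnot(is.list(mats), length(mats) >= 1)
  R <- nrow(mats[[1]])
  for (k in seq_along(mats)) {
    if (!is_spd(mats[[k]]))
      stop("matrix ", k, " is not symmetric positive definite")
    if (nrow(mats[[k]]) != R) stop("matrices have mismatched dimensions")
  }
  if (length(mats) == 1L) {
    G <- mats[[1]]
    attr(G, "iterations") <- 0L
    attr(G, "residual") <- 0
    return(G)
  }
  G <- Reduce(`+`, mats) / length(mats)
  prev_res <- Inf
  step <- 1
  for (it in seq_len(max_iter)) {
    Wi <- spd_sqrtm(G, inverse = TRUE)
    L <- Reduce(`+`, lapply(mats, function(C) spd_logm(Wi %*% C %*% Wi))) /
      length(mats)
    res <- sqrt(sum(L^2))
    if (res < tol) {
      attr(G, "iterations") <- it
      attr(G, "residual") <- res
      return(G)
    }
    if (res > prev_res) step <- step / 2 else step <- min(1, step * 1.2)
    Gh <- spd_sqrtm(G)
    G <- Gh %*% spd_expm(step * L) %*% Gh
    G <- (G + t(G)) / 2
    prev_res <- res
  }
  stop("geometric mean did not converge in ", max_iter,
       " iterations (last residual ", format(prev_res), ")")
}

#' Fit a tangent-space reference from training covariance matrices
#'
#' The reference is the geometric mean G of the training population's
#' covariance matrices together with its whitening factor W = G^{-1/2}.
#' It is frozen after fitting and reused verbatim for any external cohort
#' (the embedding is part of the trained pipeline, not of the new data).
#'
#' @param mats list of SPD covariance matrices (training subjects)
#' @param id identifier of the fit population recorded in the object
#' @inheritParams spd_geometric_mean
#' @return an object of class `tangent_reference` with elements
#'   `mean`, `whitener`, `fit_id`, `checksum`
#' @export
tangent_reference <- function(mats, id = "train", tol = 1e-7,
                              max_iter = 200) {
  G <- spd_geometric_mean(mats, tol = tol, max_iter = max_iter)
  W <- spd_sqrtm(G, inverse = TRUE)
  ref <- structure(
    list(mean = `attributes<-`(G, list(dim = dim(G))),
         whitener = W, fit_id = id),
    class = "tangent_reference")
  ref$checksum <- object_checksum(list(ref$mean, ref$whitener))
  ref
}

#' Project a covariance matrix into the tangent space at a reference
#'
#' Returns logm(W C W') where W is the reference whitener: the subject's
#' connectivity expressed as a symmetric displacement from the population
#' geometric mean. At C = G the embedding is the zero matrix.
#'
#' @param C SPD matrix
#' @param ref a `tangent_reference`
#' @return a symmetric R x R matrix
#' @export
tangent_embed <- function(C, ref) {
  stopifnot(inherits(ref, "tangent_reference"))
  if (!all(dim(C) == dim(ref$mean)))
    stop("dimension mismatch: C is ", nrow(C), "x", ncol(C),
         " but reference is ", nrow(ref$mean), "x", ncol(ref$mean))
  W <- ref$whitener
  M <- spd_logm(W %*% C %*% W)
  (M + t(M)) / 2
}

#' Flatten the strict upper triangle of a symmetric matrix
#'
#' Row-major strict upper triangle, named `edge_i_j` (1-based, i < j).
#' For R ROIs the result has length R(R-1)/2.
#'
#' @param M symmetric matrix
#' @param tol maximum tolerated asymmetry
#' @return named numeric vector
#' @export
vectorize_upper <- function(M, tol = 1e-8) {
  M <- sym_check(M, tol = tol)
  R <- nrow(M)
  idx <- upper_pairs(R)
  v <- M[idx]
  names(v) <- paste0("edge_", idx[, 1], "_", idx[, 2])
  v
}

#' @export
print.tangent_reference <- function(x, ...) {
  cat("Tangent-space reference (", nrow(x$mean), "x", ncol(x$mean),
      "), fit on '", x$fit_id, "'\n", sep = "")
  cat("  checksum:", x$checksum, "\n")
  invisible(x)
}

#' Serialize / restore a tangent reference as JSON
#' @param ref a `tangent_reference`
#' @param path file path
#' @return `read_tangent_reference` returns the restored object
#' @export
write_tangent_reference <- function(ref, path) {
  stopifnot(inherits(ref, "tangent_reference"))
  jsonlite::write_json(
    list(version = 1L, fit_id = ref$fit_id,
         dim = nrow(ref$mean),
         mean = as.vector(ref$mean), whitener = as.vector(ref$whitener)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tangent_reference
#' @export
read_tangent_reference <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- j$dim
  ref <- structure(
    list(mean = matrix(j$mean, d, d), whitener = matrix(j$whitener, d, d),
         fit_id = j$fit_id),
    class = "tangent_reference")
  ref$checksum <- object_checksum(list(ref$mean, ref$whitener))
  ref
}
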