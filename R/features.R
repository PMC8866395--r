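# Feature assembly: tangent-space edge features, anatomical vectors, and
# covariates, with training-population-only standardization. The tangent
# reference and the scaler are the two frozen preprocessing artifacts; both
# carry checksums so downstream stages can assert they were never refit.

#' Fit a standard scaler on a designated subset of rows
#'
#' Per-feature mean and standard deviation estimated on `fit_rows` only.
#' Columns constant on the fit rows are flagged and are zeroed (not divided)
#' when the scaler is applied.
#'
#' @param X numeric matrix with column names
#' @param fit_rows row indices defining the fit population
#' @return an object of class `conn_scaler`
#' @export
fit_scaler <- function(X, fit_rows = seq_len(nrow(X))) {
  stopifnot(is.matrix(X), length(fit_rows) >= 1)
  Xf <- X[fit_rows, , drop = FALSE]
  mu <- colMeans(Xf)
  sd_ <- apply(Xf, 2, stats::sd)
  constant <- !is.finite(sd_) | sd_ <= 0
  obj <- structure(list(mean = mu, sd = sd_, constant = constant,
                        features = colnames(X)), class = "conn_scaler")
  obj$checksum <- object_checksum(list(mu, sd_, constant))
  obj
}

#' Apply a frozen scaler to a feature matrix
#' @param scaler a `conn_scaler`
#' @param X matrix whose columns match the scaler's features
#' @return standardized matrix; constant-at-fit columns are set to 0
#' @export
apply_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "conn_scaler"), is.matrix(X))
  if (!identical(colnames(X), scaler$features))
    stop("feature names do not match the scaler's fit features")
  Z <- sweep(X, 2, scaler$mean)
  sd_safe <- ifelse(scaler$constant, 1, scaler$sd)
  Z <- sweep(Z, 2, sd_safe, "/")
  if (any(scaler$constant)) Z[, scaler$constant] <- 0
  attr(Z, "scaler_checksum") <- scaler$checksum
  Z
}

#' Per-subject covariance matrices of a cohort
#'
#' Computed once per subject (covariances do not depend on other subjects)
#' and cached by downstream per-fold feature building.
#'
#' @param cohort a `conn_cohort`
#' @param shrinkage passed to [estimate_covariance()]
#' @return list of SPD matrices
#' @export
cohort_covariances <- function(cohort, shrinkage = NULL) {
  lapply(cohort$subjects, function(s)
    estimate_covariance(s$timeseries, shrinkage = shrinkage))
}

#' Assemble a feature matrix for one feature-set mode
#'
#' Concatenates, in fixed order, [functional edges | anatomical | sex |
#' site one-hot]. Every mode includes the sex and site covariates. Column
#' kind tags ("functional", "anatomical", "covariate") are attached as the
#' `kinds` attribute. Site one-hot categories are fixed by `site_levels`
#' (the source cohort's sites); unseen sites map to an all-zero row with a
#' warning.
#'
#' @param mode "functional", "anatomical" or "combined"
#' @param edges n x E matrix of edge features (required unless anatomical)
#' @param anat n x A matrix of anatomical features (required unless
#'   functional)
#' @param sex binary vector length n
#' @param site integer/factor vector length n
#' @param site_levels site categories defining the one-hot columns
#' @return numeric matrix with names, `kinds` attribute
#' @export
assemble_feature_set <- function(mode = c("functional", "anatomical",
                                          "combined"),
                                 edges = NULL, anat = NULL, sex, site,
                                 site_levels = sort(unique(site))) {
  mode <- match.arg(mode)
  n <- length(sex)
  parts <- list(); kinds <- character(0)
  if (mode %in% c("functional", "combined")) {
    if (is.null(edges)) stop("mode '", mode, "' requires edge features")
    if (nrow(edges) != n) stop("subject misalignment between edges and covariates")
    parts$edges <- edges
    kinds <- c(kinds, rep("functional", ncol(edges)))
  }
  if (mode %in% c("anatomical", "combined")) {
    if (is.null(anat)) stop("mode '", mode, "' requires anatomical features")
    if (nrow(anat) != n) stop("subject misalignment between anat and covariates")
    if (is.null(colnames(anat)))
      colnames(anat) <- paste0("anat_", seq_len(ncol(anat)))
    parts$anat <- anat
    kinds <- c(kinds, rep("anatomical", ncol(anat)))
  }
  sexm <- matrix(as.numeric(sex), ncol = 1,
                 dimnames = list(NULL, "cov_sex"))
  if (any(!site %in% site_levels))
    warning("sites not present in the source cohort map to all-zero rows: ",
            paste(unique(site[!site %in% site_levels]), collapse = ", "))
  oh <- vapply(site_levels, function(l) as.numeric(site == l), numeric(n))
  if (!is.matrix(oh)) oh <- matrix(oh, nrow = n)
  colnames(oh) <- paste0("cov_site_", site_levels)
  parts$cov <- cbind(sexm, oh)
  kinds <- c(kinds, rep("covariate", ncol(parts$cov)))
  X <- do.call(cbind, parts)
  if (anyDuplicated(colnames(X))) stop("duplicate feature names")
  attr(X, "kinds") <- kinds
  X
}

#' Build standardized features for a cohort with preprocessing fit on a
#' designated population
#'
#' The tangent reference is fit by Riemannian geometric mean over the
#' covariances of `fit_idx` subjects only, and the scaler over the rows of
#' `fit_idx` only; both are then applied to all subjects. This is the
#' leakage-safe path used inside cross-validation folds (fit on the fold's
#' training portion) and for final test scoring (fit on the full training
#' set).
#'
#' @param cohort a `conn_cohort`
#' @param mode feature-set mode
#' @param fit_idx indices of the preprocessing fit population
#' @param covs optional precomputed [cohort_covariances()] list
#' @param ref optional frozen `tangent_reference` (external evaluation);
#'   when supplied with `scaler`, nothing is refit
#' @param scaler optional frozen `conn_scaler`
#' @param site_levels site categories for the one-hot encoding
#' @return list with `X` (standardized matrix), `ref`, `scaler`, `kinds`
#' @export
build_features <- function(cohort, mode = "functional",
                           fit_idx = seq_along(cohort$subjects),
                           covs = NULL, ref = NULL, scaler = NULL,
                           site_levels = NULL) {
  needs_edges <- mode %in% c("functional", "combined")
  edges <- NULL
  if (needs_edges) {
    if (is.null(covs)) covs <- cohort_covariances(cohort)
    if (is.null(ref)) ref <- tangent_reference(covs[fit_idx])
    edges <- t(vapply(covs, function(C) vectorize_upper(tangent_embed(C, ref)),
                      numeric(nrow(ref$mean) * (nrow(ref$mean) - 1) / 2)))
  }
  anat <- NULL
  if (mode %in% c("anatomical", "combined")) anat <- cohort_anat(cohort)
  site <- cohort_site(cohort)
  if (is.null(site_levels)) site_levels <- sort(unique(site[fit_idx]))
  X <- assemble_feature_set(mode, edges = edges, anat = anat,
                            sex = cohort_sex(cohort), site = site,
                            site_levels = site_levels)
  kinds <- attr(X, "kinds")
  if (is.null(scaler)) scaler <- fit_scaler(X, fit_idx)
  Z <- apply_scaler(scaler, X)
  attr(Z, "kinds") <- kinds
  if (!is.null(ref)) attr(Z, "reference_checksum") <- ref$checksum
  list(X = Z, ref = ref, scaler = scaler, kinds = kinds,
       site_levels = site_levels)
}

#' Serialize / restore a scaler as JSON
#' @param scaler a `conn_scaler`
#' @param path file path
#' @export
write_scaler <- function(scaler, path) {
  jsonlite::write_json(
    list(version = 1L, features = scaler$features, mean = scaler$mean,
         sd = scaler$sd, constant = scaler$constant),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj <- structure(list(mean = stats::setNames(j$mean, j$features),
                        sd = stats::setNames(j$sd, j$features),
                        constant = stats::setNames(as.logical(j$constant),
                                                   j$features),
                        features = j$features), class = "conn_scaler")
  obj$checksum <- object_checksum(list(obj$mean, obj$sd, obj$constant))
  obj
}
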