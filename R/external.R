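# External-cohort evaluation: transfer without adaptation (with frozen
# preprocessing artifacts and a leakage guard), supervised domain
# adaptation by warm-start fine-tuning on a small labelled slice, and
# pre/post importance concordance.

#' Build external-cohort features with the source pipeline's frozen
#' artifacts
#'
#' @param cohort the external `conn_cohort`
#' @param mode feature-set mode (must match the source models')
#' @param ref the source `tangent_reference`
#' @param scaler the source `conn_scaler`
#' @param site_levels the source cohort's site categories
#' @param shrinkage covariance shrinkage
#' @return list as from [build_features()]
#' @export
external_features <- function(cohort, mode, ref, scaler, site_levels,
                              shrinkage = NULL) {
  build_features(cohort, mode, covs = cohort_covariances(cohort, shrinkage),
                 ref = ref, scaler = scaler, site_levels = site_levels)
}

check_artifacts <- function(model, ref, scaler) {
  ck <- model$artifact_checksums
  if (is.null(ck)) return(invisible(TRUE))
  if (!is.null(ck$reference) && !is.null(ref) &&
      !identical(ck$reference, ref$checksum))
    stop("leakage guard: tangent reference checksum does not match the ",
         "one this model was trained with")
  if (!is.null(ck$scaler) && !identical(ck$scaler, scaler$checksum))
    stop("leakage guard: scaler checksum does not match the one this ",
         "model was trained with")
  invisible(TRUE)
}

#' Evaluate source-trained models on an external cohort without adaptation
#'
#' Features must be built with the source tangent reference and scaler
#' (see [external_features()]); each model's stored artifact checksums are
#' verified against the supplied artifacts before scoring (hard error on
#' mismatch — the external cohort must never refit the preprocessing).
#'
#' @param models list of `conn_model`s (e.g. the top-5 of a family)
#' @param X external feature matrix
#' @param y external labels
#' @param ref,scaler the frozen source artifacts used to build `X`
#' @return object of class `transfer_result`: per-model AUROC, mean, sd
#' @export
transfer_evaluate <- function(models, X, y, ref = NULL, scaler = NULL) {
  if (inherits(models, "conn_model")) models <- list(models)
  auroc <- vapply(models, function(m) {
    if (!is.null(scaler)) check_artifacts(m, ref, scaler)
    compute_auroc(predict_score(m, X), y)
  }, 0)
  structure(list(auroc = auroc, mean = mean(auroc),
                 sd = if (length(auroc) > 1) stats::sd(auroc) else NA_real_,
                 n_models = length(models),
                 reference_checksum = if (!is.null(ref)) ref$checksum,
                 scaler_checksum = if (!is.null(scaler)) scaler$checksum),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("Transfer evaluation (no adaptation), ", x$n_models, " model(s)\n",
      sep = "")
  cat("  AUROC: ", paste(sprintf("%.3f", x$auroc), collapse = ", "),
      "\n  mean +/- sd: ", sprintf("%.3f +/- %.3f", x$mean, x$sd), "\n",
      sep = "")
  invisible(x)
}

#' Supervised domain adaptation on an external cohort
#'
#' Ten-fold scheme: the cohort is partitioned into `k` deciles; in fold i
#' the model is tuned on decile i (a `tune_frac` = 10% slice) and tested
#' on the remaining 90%, so every subject appears in exactly k-1 test
#' sets. Neural families fine-tune from their trained weights with early
#' stopping monitored on a stratified sliver of the tuning slice;
#' classical families have no warm start and are refit from scratch on the
#' tuning slice (flagged in the result). Folds whose tuning slice misses a
#' class are skipped and logged.
#'
#' @param model a `conn_model` trained on the source cohort
#' @param X,y external features (built with the frozen source artifacts)
#'   and labels
#' @param k number of folds (deciles)
#' @param seed seed for the fold partition and fine-tuning
#' @param max_epochs fine-tuning epoch budget; 0 is a no-op adaptation
#'   whose per-fold AUROC equals the transfer AUROC on that fold's test set
#' @param lr fine-tuning learning rate
#' @return object of class `adaptation_result`: per-fold tuned AUROC and
#'   the matching per-fold transfer AUROC, means, sds, `mode`
#'   ("fine_tune" or "refit"), skipped folds
#' @export
domain_adapt <- function(model, X, y, k = 10, seed = 1L, max_epochs = 50,
                         lr = 1e-4) {
  stopifnot(inherits(model, "conn_model"))
  y <- as.integer(y)
  n <- nrow(X)
  deep <- model$family %in% c("dfnn", "lstm", "brainnet_cnn")
  folds <- with_seed(substream_seed(seed, 5L, salt = 91L), {
    f <- integer(n)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      f[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  kinds <- attr(X, "kinds")
  tuned_auroc <- transfer_auroc <- rep(NA_real_, k)
  skipped <- integer(0)
  for (f in seq_len(k)) {
    tune_idx <- which(folds == f)
    test_idx <- which(folds != f)
    if (length(unique(y[tune_idx])) < 2) {
      skipped <- c(skipped, f)
      next
    }
    Xtu <- X[tune_idx, , drop = FALSE]; attr(Xtu, "kinds") <- kinds
    Xte <- X[test_idx, , drop = FALSE]; attr(Xte, "kinds") <- kinds
    transfer_auroc[f] <- compute_auroc(predict_score(model, Xte),
                                       y[test_idx])
    tuned <- if (deep) {
      fine_tune_model(model, Xtu, y[tune_idx], max_epochs = max_epochs,
                      lr = lr, seed = substream_seed(seed, f, salt = 92L))
    } else {
      fit_model(model$family, model$config, Xtu, y[tune_idx],
                seed = substream_seed(seed, f, salt = 92L))
    }
    tuned_auroc[f] <- compute_auroc(predict_score(tuned, Xte), y[test_idx])
  }
  ok <- !is.na(tuned_auroc)
  structure(list(tuned_auroc = tuned_auroc,
                 transfer_auroc = transfer_auroc,
                 mean = mean(tuned_auroc[ok]), sd = stats::sd(tuned_auroc[ok]),
                 transfer_mean = mean(transfer_auroc[ok]),
                 transfer_sd = stats::sd(transfer_auroc[ok]),
                 k = k, tune_frac = 1 / k,
                 mode = if (deep) "fine_tune" else "refit",
                 skipped = skipped, folds = folds,
                 seed = as.integer(seed)),
            class = "adaptation_result")
}

#' @export
print.adaptation_result <- function(x, ...) {
  cat("Supervised domain adaptation (", x$mode, "), ", x$k,
      "-fold, tune fraction ", sprintf("%.0f%%", 100 * x$tune_frac), "\n",
      sep = "")
  cat(sprintf("  tuned AUROC:    %.3f +/- %.3f\n", x$mean, x$sd))
  cat(sprintf("  transfer AUROC: %.3f +/- %.3f\n",
              x$transfer_mean, x$transfer_sd))
  if (length(x$skipped))
    cat("  skipped folds:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Concordance of feature importances before and after adaptation
#'
#' Restricts to features significant (z above `z_threshold`) in either the
#' pre- or the post-adaptation importances (union; `subset =
#' "intersection"` uses features significant in both) and reports Pearson
#' and Spearman correlations of the mean importances on that subset.
#'
#' @param pre,post `conn_importance` objects on one feature namespace
#' @param z_threshold significance threshold on z (default 3)
#' @param subset "union" or "intersection"
#' @return object of class `concordance_result` with `pearson`,
#'   `spearman`, the feature subset and its size; correlations are NA with
#'   a flag when the subset has fewer than 3 features
#' @export
importance_concordance <- function(pre, post, z_threshold = 3,
                                   subset = c("union", "intersection")) {
  subset <- match.arg(subset)
  stopifnot(inherits(pre, "conn_importance"),
            inherits(post, "conn_importance"))
  if (!identical(sort(pre$feature), sort(post$feature)))
    stop("importance objects do not share one feature namespace")
  post <- post[match(pre$feature, post$feature), ]
  sel_pre <- pre$z > z_threshold
  sel_post <- post$z > z_threshold
  sel <- if (subset == "union") sel_pre | sel_post else sel_pre & sel_post
  feats <- pre$feature[sel]
  if (sum(sel) < 3) {
    return(structure(list(pearson = NA_real_, spearman = NA_real_,
                          features = feats, n = sum(sel),
                          subset = subset, undefined = TRUE,
                          z_threshold = z_threshold),
                     class = "concordance_result"))
  }
  a <- pre$mean_importance[sel]; b <- post$mean_importance[sel]
  structure(list(pearson = stats::cor(a, b, method = "pearson"),
                 spearman = stats::cor(a, b, method = "spearman"),
                 features = feats, n = sum(sel), subset = subset,
                 undefined = FALSE, z_threshold = z_threshold),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Importance concordance over ", x$n, " significant feature(s) (",
      x$subset, ", z > ", x$z_threshold, ")\n", sep = "")
  if (x$undefined) cat("  fewer than 3 features: correlations undefined\n")
  else cat(sprintf("  Pearson R = %.3f, Spearman R = %.3f\n",
                   x$pearson, x$spearman))
  invisible(x)
}
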