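# Permutation feature importance (PFI) with a label-permutation null,
# Benjamini-Yekutieli FDR control, cross-model consensus ranking, and
# univariate direction marking: the biomarker-discovery core.
#
# Importance of a feature is the mean decrease in AUROC when that feature
# alone is permuted across subjects, I = AUROC_b - AUROC_a, averaged over
# n_reps independent permutations; z-scores are computed across features
# from the per-feature means.

# stable per-feature stream key from the feature NAME, so the importance of
# a feature is invariant to which other features are analyzed and to column
# order
feature_stream <- function(name) {
  chars <- utf8ToInt(name)
  h <- 7
  for (c in chars) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

#' Permutation feature importance of a fitted model
#'
#' For every feature, `n_reps` independent permutations of that column are
#' applied (all other columns untouched), the model is rescored and the
#' AUROC drop recorded. Permutations for feature j come from a dedicated
#' RNG stream keyed by the feature's name, so results for one feature do
#' not depend on the presence or order of others.
#'
#' @param model a `conn_model`
#' @param X feature matrix (conventionally the held-out test rows)
#' @param y binary labels for `X`
#' @param n_reps permutation repetitions per feature (>= 2)
#' @param seed seed
#' @param features subset of feature names to analyze (default all)
#' @param chunk permutations scored per prediction call (memory knob)
#' @return object of class `conn_importance`: data frame with columns
#'   `feature`, `mean_importance`, `z` (and after [significance()] also
#'   `p`, `q`, `significant`); the per-repetition importance matrix is in
#'   `attr(, "reps")` (n_reps x n_features), the unpermuted AUROC in
#'   `attr(, "auroc_base")`
#' @export
permutation_importance <- function(model, X, y, n_reps = 64, seed = 1L,
                                   features = colnames(X), chunk = 16L) {
  stopifnot(inherits(model, "conn_model"), is.matrix(X))
  if (n_reps < 2) stop("n_reps must be at least 2")
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(X)
  kinds <- attr(X, "kinds")
  auroc_b <- compute_auroc(predict_score(model, X), y)
  p <- length(features)
  reps <- matrix(NA_real_, n_reps, p, dimnames = list(NULL, features))
  for (j in seq_len(p)) {
    fname <- features[j]
    col <- match(fname, colnames(X))
    if (is.na(col)) stop("feature not in X: ", fname)
    perms <- with_seed(substream_seed(seed, feature_stream(fname)),
                       replicate(n_reps, sample.int(n), simplify = FALSE))
    r <- 1L
    while (r <= n_reps) {
      rr <- r:min(r + chunk - 1L, n_reps)
      Xs <- X[rep(seq_len(n), length(rr)), , drop = FALSE]
      for (b in seq_along(rr)) {
        rows <- (b - 1L) * n + seq_len(n)
        Xs[rows, col] <- X[perms[[rr[b]]], col]
      }
      attr(Xs, "kinds") <- kinds
      sc <- predict_score(model, Xs)
      for (b in seq_along(rr))
        reps[rr[b], j] <- auroc_b -
          compute_auroc(sc[(b - 1L) * n + seq_len(n)], y)
      r <- r + length(rr)
    }
  }
  means <- colMeans(reps)
  z <- as.numeric(scale(means))
  out <- data.frame(feature = features, mean_importance = means, z = z,
                    row.names = NULL)
  attr(out, "reps") <- reps
  attr(out, "auroc_base") <- auroc_b
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  class(out) <- c("conn_importance", "data.frame")
  out
}

#' Label-permutation null distribution of feature importance
#'
#' For each of `n_label_perms` permutations of the training labels, the
#' model is refit and permutation feature importance is computed exactly as
#' for the real model; the resulting per-feature mean importances are
#' pooled into one null sample. Refit failures are skipped and logged; at
#' least 80% of the permutations must succeed.
#'
#' @param family,config model family and configuration to refit
#' @param X_fit,y_fit training rows (labels are permuted here)
#' @param X_eval,y_eval evaluation rows for the importance computation
#' @param n_label_perms number of label permutations
#' @param n_reps permutation repetitions inside each importance run
#' @param seed seed
#' @param features feature subset (default all)
#' @return object of class `conn_null`: list with pooled `values`,
#'   `n_perms`, `n_success`, `seed`
#' @export
build_null <- function(family, config, X_fit, y_fit, X_eval, y_eval,
                       n_label_perms = 20, n_reps = 64, seed = 1L,
                       features = colnames(X_eval)) {
  values <- numeric(0)
  n_success <- 0L
  failures <- character(0)
  for (b in seq_len(n_label_perms)) {
    perm_seed <- substream_seed(seed, b, salt = 71L)
    y_perm <- with_seed(perm_seed, sample(y_fit))
    res <- tryCatch({
      m <- fit_model(family, config, X_fit, y_perm, seed = perm_seed)
      imp <- permutation_importance(m, X_eval, y_eval, n_reps = n_reps,
                                    seed = perm_seed, features = features)
      imp$mean_importance
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    values <- c(values, res)
    n_success <- n_success + 1L
  }
  if (n_success < 0.8 * n_label_perms)
    stop("only ", n_success, "/", n_label_perms,
         " null refits succeeded (>= 80% required); first failure: ",
         failures[1])
  structure(list(values = values, n_perms = n_label_perms,
                 n_success = n_success, seed = as.integer(seed),
                 failures = failures), class = "conn_null")
}

#' @export
print.conn_null <- function(x, ...) {
  cat("Importance null distribution: ", length(x$values), " pooled values ",
      "from ", x$n_success, "/", x$n_perms, " label permutations\n",
      sep = "")
  invisible(x)
}

#' Significance of feature importances against a null distribution
#'
#' Each feature's mean importance is compared with the pooled null sample
#' by a one-tailed t-test in prediction form: under the null hypothesis
#' the observed mean is one more draw from the null population, so
#' t = (I_j - mean(null)) / (sd(null) * sqrt(1 + 1/n_null)) with
#' n_null - 1 degrees of freedom, alternative "greater". Using the null
#' sample's spread (which carries the between-feature and between-refit
#' variability of chance importances) keeps the test calibrated — the
#' repetition values within one feature are strongly correlated and their
#' naive standard error would be far too small. P-values are adjusted with
#' the Benjamini-Yekutieli step-up procedure (valid under arbitrary
#' dependence); a feature is significant when its q-value is at most
#' `fdr_rate`. Degenerate (zero-variance) repetition samples get p = 1 and
#' a flag.
#'
#' @param imp a `conn_importance`
#' @param null a `conn_null`
#' @param fdr_rate FDR level (default 1%)
#' @return the importance object with `p`, `q`, `significant`, `degenerate`
#'   columns filled
#' @export
significance <- function(imp, null, fdr_rate = 0.01) {
  stopifnot(inherits(imp, "conn_importance"), inherits(null, "conn_null"))
  if (length(null$values) == 0) stop("null distribution is empty")
  reps <- attr(imp, "reps")
  n0 <- length(null$values)
  m0 <- mean(null$values)
  s0 <- stats::sd(null$values)
  p <- vapply(seq_len(ncol(reps)), function(j) {
    if (s0 == 0) return(if (mean(reps[, j]) > m0) 0 else 1)
    tj <- (mean(reps[, j]) - m0) / (s0 * sqrt(1 + 1 / n0))
    stats::pt(tj, df = n0 - 1, lower.tail = FALSE)
  }, 0)
  degenerate <- apply(reps, 2, stats::sd) == 0
  p[degenerate] <- 1
  imp$p <- p
  imp$q <- stats::p.adjust(p, method = "BY")
  imp$significant <- imp$q <= fdr_rate
  imp$degenerate <- degenerate
  attr(imp, "fdr_rate") <- fdr_rate
  imp
}

#' Consensus biomarker ranking across top models
#'
#' Features are ranked by their median z-scored importance across the
#' supplied models (typically the top 5 configurations of the best
#' family). A feature is starred when every model gives it z >= `z_flag`,
#' and marked with a diamond when all but one do.
#'
#' @param imp_list list of >= 2 `conn_importance` objects sharing one
#'   feature namespace
#' @param top_k number of features returned (default 15)
#' @param z_flag z threshold for the reproducibility flags
#' @return data frame of class `conn_consensus`: `feature`, `median_z`,
#'   `n_above`, `star`, `diamond`, plus one `z_model<i>` column per model,
#'   ordered by decreasing median z
#' @export
consensus_rank <- function(imp_list, top_k = 15, z_flag = 3) {
  stopifnot(is.list(imp_list), length(imp_list) >= 2)
  feats <- imp_list[[1]]$feature
  for (im in imp_list)
    if (!identical(sort(im$feature), sort(feats)))
      stop("importance objects do not share one feature namespace")
  zmat <- vapply(imp_list, function(im)
    im$z[match(feats, im$feature)], numeric(length(feats)))
  med <- apply(zmat, 1, stats::median)
  n_above <- rowSums(zmat >= z_flag)
  k <- length(imp_list)
  out <- data.frame(feature = feats, median_z = med, n_above = n_above,
                    star = n_above == k, diamond = n_above == k - 1,
                    row.names = NULL)
  colnames(zmat) <- paste0("z_model", seq_len(k))
  out <- cbind(out, zmat)
  out <- out[order(-out$median_z), , drop = FALSE]
  out <- utils::head(out, top_k)
  rownames(out) <- NULL
  class(out) <- c("conn_consensus", "data.frame")
  out
}

#' Univariate direction of a feature between diagnostic groups
#'
#' Welch two-sample two-tailed t-test of the feature between cases and
#' controls: "+" if the case mean is higher and p <= alpha, "-" if lower
#' and p <= alpha, "o" otherwise.
#'
#' @param X feature matrix
#' @param y binary labels (1 = case)
#' @param feature feature name or column index
#' @param alpha significance level (default 0.05)
#' @return list with `mark` ("+", "-" or "o"), `p`, `t`, `case_mean`,
#'   `control_mean`
#' @export
direction_mark <- function(X, y, feature, alpha = 0.05) {
  x <- if (is.character(feature)) X[, feature] else X[, feature]
  y <- as.integer(y)
  x1 <- x[y == 1L]; x0 <- x[y == 0L]
  if (length(x1) == 0 || length(x0) == 0) stop("both groups must be nonempty")
  if (stats::sd(x1) == 0 && stats::sd(x0) == 0)
    stop("zero within-group variance in both groups")
  tt <- stats::t.test(x1, x0)
  mark <- if (tt$p.value <= alpha) {
    if (mean(x1) > mean(x0)) "+" else "-"
  } else "o"
  list(mark = mark, p = tt$p.value, t = unname(tt$statistic),
       case_mean = mean(x1), control_mean = mean(x0))
}
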