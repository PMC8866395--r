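# The fairness-preserving experiment engine: one frozen split plan shared
# by every family, a fixed number of randomly drawn configurations per
# (family x feature set), selection by mean cross-validation AUROC, a
# single held-out test evaluation of the selected configuration, and a
# kernel-density landscape analysis of the search records.

#' Run the random hyperparameter search over a cohort
#'
#' For every (family x feature set) combination, `n_configs` configurations
#' are drawn from the family's search space and each is trained on the
#' training portion of each of the plan's CV folds and scored on the fold's
#' validation portion by AUROC. The configuration with the highest mean CV
#' AUROC (ties broken by smaller draw index) is refit on the full training
#' set and evaluated once on the held-out test set.
#'
#' Preprocessing is leakage-safe: the tangent reference and the scaler are
#' refit inside each fold's training portion for validation scoring
#' (`refit_mode = "per_fold"`, default) and on the full training set for
#' test scoring. `refit_mode = "global"` instead freezes both on the full
#' training set for all folds.
#'
#' The connectome CNN only accepts functional connectivity input; its cells
#' for anatomical/combined feature sets are skipped (NA in the result
#' matrix).
#'
#' @param cohort a `conn_cohort`
#' @param families character vector of family names
#' @param feature_sets subset of c("functional", "anatomical", "combined")
#' @param n_configs configurations drawn per (family x feature set)
#' @param plan a `split_plan` built on this cohort (frozen; its checksum is
#'   recorded in every search record)
#' @param seed master seed for config draws and fits
#' @param refit_mode "per_fold" or "global" preprocessing refit policy
#' @param journal optional path to an append-only JSON-lines journal;
#'   completed (family, feature set, config) evaluations found there are
#'   reused, so an interrupted search resumes without retraining
#' @param keep_models keep the refit best model per cell in the result
#'   (needed by the importance and external-validation stages)
#' @param shrinkage covariance shrinkage passed to [estimate_covariance()]
#' @param verbose print progress
#' @return an object of class `conn_search`: list with `records` (one row
#'   per evaluated config), `result_matrix` (family x feature set test
#'   AUROC), `best` (per-cell best config + model + frozen artifacts),
#'   `plan`, `seed`
#' @export
run_search <- function(cohort, families, feature_sets = "functional",
                       n_configs = 50, plan, seed = 1L,
                       refit_mode = c("per_fold", "global"),
                       journal = NULL, keep_models = TRUE,
                       shrinkage = NULL, verbose = FALSE) {
  refit_mode <- match.arg(refit_mode)
  stopifnot(inherits(plan, "split_plan"))
  fams <- model_families()
  bad <- setdiff(families, fams$family)
  if (length(bad)) stop("unknown families: ", paste(bad, collapse = ", "))
  y <- cohort_labels(cohort)
  stopifnot(length(y) == plan$n)

  covs <- cohort_covariances(cohort, shrinkage = shrinkage)
  site_levels <- sort(unique(cohort_site(cohort)[plan$train]))

  # features per (mode x fit population); fit populations: each fold's
  # training portion and the full training set
  feat_cache <- new.env(parent = emptyenv())
  features_for <- function(mode, fit_idx, key) {
    if (is.null(feat_cache[[key]]))
      feat_cache[[key]] <- build_features(
        cohort, mode, fit_idx = fit_idx, covs = covs,
        site_levels = site_levels)
    feat_cache[[key]]
  }

  done <- journal_read(journal)
  records <- list()
  best_cells <- list()
  rm_mat <- matrix(NA_real_, length(families), length(feature_sets),
                   dimnames = list(families, feature_sets))

  for (mode in feature_sets) {
    full <- features_for(mode, plan$train, paste0(mode, "::train"))
    fold_feats <- lapply(seq_len(plan$k), function(f) {
      fit_idx <- plan$train[plan$folds != f]
      features_for(mode, fit_idx, paste0(mode, "::fold", f))
    })
    for (family in families) {
      if (fams$square_input[fams$family == family] &&
          mode != "functional") {
        msg("skip %s x %s (square-input family)", family, mode,
            verbose = verbose)
        next
      }
      cell_records <- vector("list", n_configs)
      for (ci in seq_len(n_configs)) {
        cfg_seed <- substream_seed(seed, ci,
                                   salt = substream_seed(
                                     match(family, fams$family),
                                     match(mode, c("functional",
                                                   "anatomical",
                                                   "combined"))))
        config <- sample_config(family, seed = cfg_seed, draw_index = ci)
        key <- journal_key(family, mode, ci)
        if (!is.null(done[[key]])) {
          rec <- done[[key]]
          rec$config <- config
          cell_records[[ci]] <- rec
          next
        }
        fold_auroc <- rep(NA_real_, plan$k)
        failed <- FALSE
        for (f in seq_len(plan$k)) {
          fit_idx <- plan$train[plan$folds != f]
          val_idx <- plan$train[plan$folds == f]
          fe <- fold_feats[[f]]
          Xf <- fe$X[fit_idx, , drop = FALSE]
          attr(Xf, "kinds") <- fe$kinds
          Xv <- fe$X[val_idx, , drop = FALSE]
          attr(Xv, "kinds") <- fe$kinds
          res <- tryCatch({
            m <- fit_model(family, config, Xf, y[fit_idx],
                           seed = cfg_seed, X_val = Xv, y_val = y[val_idx])
            compute_auroc(predict_score(m, Xv), y[val_idx])
          }, error = function(e) e)
          if (inherits(res, "error")) {
            failed <- TRUE
            msg("config %d fold %d failed: %s", ci, f,
                conditionMessage(res), verbose = verbose)
            break
          }
          fold_auroc[f] <- res
        }
        rec <- list(family = family, feature_set = mode, config_index = ci,
                    config_seed = cfg_seed,
                    values = config$values,
                    fold_auroc = fold_auroc,
                    mean_cv_auroc = if (failed) NA_real_
                                    else mean(fold_auroc),
                    failed = failed, test_auroc = NA_real_,
                    plan_checksum = plan$checksum,
                    config = config)
        journal_append(journal, key, rec)
        cell_records[[ci]] <- rec
      }
      means <- vapply(cell_records, function(r)
        if (isTRUE(r$failed)) -Inf else r$mean_cv_auroc, 0)
      if (all(!is.finite(means))) {
        warning("all configs failed for ", family, " x ", mode)
        records <- c(records, cell_records)
        next
      }
      best_ci <- which.max(means)  # which.max takes the first maximum:
                                   # ties break toward the smaller index
      best_cfg <- cell_records[[best_ci]]$config
      Xtr <- full$X[plan$train, , drop = FALSE]
      attr(Xtr, "kinds") <- full$kinds
      Xte <- full$X[plan$test, , drop = FALSE]
      attr(Xte, "kinds") <- full$kinds
      m <- fit_model(family, best_cfg, Xtr, y[plan$train],
                     seed = cell_records[[best_ci]]$config_seed,
                     artifact_checksums = list(
                       reference = if (!is.null(full$ref))
                         full$ref$checksum,
                       scaler = full$scaler$checksum))
      test_auroc <- compute_auroc(predict_score(m, Xte), y[plan$test])
      cell_records[[best_ci]]$test_auroc <- test_auroc
      cell_records[[best_ci]]$selected <- TRUE
      rm_mat[family, mode] <- test_auroc
      best_cells[[paste(family, mode, sep = "::")]] <- list(
        family = family, feature_set = mode,
        config = best_cfg, config_index = best_ci,
        config_seed = cell_records[[best_ci]]$config_seed,
        mean_cv_auroc = cell_records[[best_ci]]$mean_cv_auroc,
        test_auroc = test_auroc,
        model = if (keep_models) m,
        ref = full$ref, scaler = full$scaler, kinds = full$kinds,
        site_levels = full$site_levels)
      msg("%s x %s: best config %d, CV %.3f, test %.3f", family, mode,
          best_ci, cell_records[[best_ci]]$mean_cv_auroc, test_auroc,
          verbose = verbose)
      records <- c(records, cell_records)
    }
  }

  structure(list(records = records, result_matrix = rm_mat,
                 best = best_cells, plan = plan, seed = as.integer(seed),
                 families = families, feature_sets = feature_sets,
                 n_configs = n_configs, refit_mode = refit_mode),
            class = "conn_search")
}

journal_key <- function(family, mode, ci) {
  paste(family, mode, ci, sep = "::")
}

journal_read <- function(path) {
  done <- list()
  if (is.null(path) || !file.exists(path)) return(done)
  for (ln in readLines(path, warn = FALSE)) {
    if (!nzchar(ln)) next
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    rec$values <- as.list(rec$values)
    rec$mean_cv_auroc <- as.numeric(rec$mean_cv_auroc %||% NA_real_)
    rec$test_auroc <- as.numeric(rec$test_auroc %||% NA_real_)
    rec$fold_auroc <- as.numeric(rec$fold_auroc)
    done[[journal_key(rec$family, rec$feature_set, rec$config_index)]] <- rec
  }
  done
}

journal_append <- function(path, key, rec) {
  if (is.null(path)) return(invisible())
  keep <- rec[c("family", "feature_set", "config_index", "config_seed",
                "values", "fold_auroc", "mean_cv_auroc", "failed",
                "test_auroc", "plan_checksum")]
  cat(jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null"),
      "\n", sep = "", file = path, append = TRUE)
  invisible()
}

#' Search records as a data frame
#' @param x a `conn_search`
#' @param ... unused
#' @return data frame, one row per evaluated configuration
#' @export
search_records <- function(x, ...) {
  stopifnot(inherits(x, "conn_search"))
  do.call(rbind, lapply(x$records, function(r) {
    data.frame(family = r$family, feature_set = r$feature_set,
               config_index = r$config_index,
               mean_cv_auroc = r$mean_cv_auroc,
               test_auroc = r$test_auroc,
               selected = isTRUE(r$selected),
               failed = isTRUE(r$failed),
               plan_checksum = r$plan_checksum)
  }))
}

#' @export
print.conn_search <- function(x, ...) {
  cat("Hyperparameter search: ", length(x$families), " families x ",
      length(x$feature_sets), " feature sets x ", x$n_configs,
      " configs (", length(x$records), " records)\n", sep = "")
  cat("Held-out test AUROC:\n")
  print(round(x$result_matrix, 3))
  invisible(x)
}

#' @export
summary.conn_search <- function(object, ...) {
  df <- search_records(object)
  agg <- stats::aggregate(mean_cv_auroc ~ family + feature_set, df, mean)
  names(agg)[3] <- "mean_cv_auroc_over_configs"
  sel <- df[df$selected, c("family", "feature_set", "config_index",
                           "mean_cv_auroc", "test_auroc")]
  out <- list(result_matrix = object$result_matrix, selected = sel,
              config_mean = agg)
  class(out) <- "summary.conn_search"
  out
}

#' @export
print.summary.conn_search <- function(x, ...) {
  cat("Selected configurations (held-out test AUROC):\n")
  print(x$selected, row.names = FALSE)
  invisible(x)
}

#' Heat-table plot of the search result matrix
#' @param x a `conn_search`
#' @param ... passed to [graphics::image()]
#' @export
plot.conn_search <- function(x, ...) {
  m <- x$result_matrix
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  axes = FALSE, xlab = "feature set", ylab = "family",
                  col = grDevices::hcl.colors(32, "Greens", rev = TRUE),
                  ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m))
  graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 2)
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    if (is.finite(m[i, j]))
      graphics::text(j, i, sprintf("%.2f", m[i, j]))
  invisible(x)
}

#' Kernel-density landscape of a hyperparameter search
#'
#' Splits the records into the top and bottom performance quantiles (by
#' mean CV AUROC; each quantile set has ceiling(q * n) records) and
#' estimates a kernel density over the requested hyperparameter dimensions
#' for each set: 1-D via [stats::density()], 2-D via [MASS::kde2d()], both
#' with normal-reference (Scott-style) bandwidths. Log-scaled dimensions
#' are analyzed on log10. The located density peak is flagged when it lies
#' within 5% of a search boundary.
#'
#' @param records a `conn_search`, or a data frame with a `mean_cv_auroc`
#'   column and one column per hyperparameter dimension
#' @param dims one or two dimension names
#' @param quantile_frac quantile fraction (default top/bottom 20%)
#' @param bounds optional named list of c(lo, hi) per dim; defaults to the
#'   observed range over all records
#' @param log_dims dims analyzed on log10 scale (default: auto-detected
#'   from the family's space when `records` is a `conn_search`)
#' @param n_grid evaluation grid size per dimension
#' @param family restrict a `conn_search` to one family's records
#' @return an object of class `conn_landscape` with per-quantile density
#'   grids, peak locations and boundary flags
#' @export
landscape_kde <- function(records, dims, quantile_frac = 0.2, bounds = NULL,
                          log_dims = NULL, n_grid = 64, family = NULL) {
  if (inherits(records, "conn_search")) {
    recs <- records$records
    if (!is.null(family)) recs <- Filter(function(r) r$family == family, recs)
    if (is.null(log_dims) && length(recs)) {
      space <- hyperparameter_space(recs[[1]]$family)
      log_dims <- names(space)[vapply(space, function(d)
        identical(d$scale, "log"), TRUE)]
    }
    df <- do.call(rbind, lapply(recs, function(r)
      cbind(data.frame(mean_cv_auroc = r$mean_cv_auroc),
            as.data.frame(r$values))))
  } else df <- records
  log_dims <- intersect(log_dims %||% character(0), dims)
  stopifnot(length(dims) %in% 1:2, all(dims %in% names(df)))
  df <- df[is.finite(df$mean_cv_auroc), , drop = FALSE]
  n <- nrow(df)
  if (n < 10) stop("need at least 10 usable records")
  n_q <- ceiling(quantile_frac * n)
  ord <- order(df$mean_cv_auroc, decreasing = TRUE)
  top <- df[ord[seq_len(n_q)], , drop = FALSE]
  bottom <- df[ord[(n - n_q + 1):n], , drop = FALSE]
  degenerate <- max(df$mean_cv_auroc) - min(df$mean_cv_auroc) < 1e-12

  tf <- function(v, d) if (d %in% log_dims) log10(v) else v
  lims <- lapply(dims, function(d) {
    b <- bounds[[d]] %||% range(df[[d]])
    tf(b, d)
  })
  names(lims) <- dims

  # bandwidths are floored at a fraction of the search range so that a
  # quantile set concentrated on one (e.g. integer) value still yields a
  # peak resolvable on the evaluation grid
  kde_set <- function(sub) {
    if (length(dims) == 1) {
      x <- tf(sub[[dims]], dims)
      bw_ref <- tryCatch(stats::bw.nrd(x), error = function(e) 0)
      bw <- max(bw_ref, diff(lims[[1]]) / 32)
      de <- stats::density(x, bw = bw, from = lims[[1]][1],
                           to = lims[[1]][2], n = n_grid)
      peak_i <- which.max(de$y)
      list(grid = list(de$x), density = de$y,
           peak = stats::setNames(de$x[peak_i], dims))
    } else {
      x <- tf(sub[[dims[1]]], dims[1]); y <- tf(sub[[dims[2]]], dims[2])
      h_ref <- function(v) tryCatch(MASS::bandwidth.nrd(v),
                                    error = function(e) 0)
      h <- c(max(h_ref(x), diff(lims[[1]]) / 8),
             max(h_ref(y), diff(lims[[2]]) / 8))
      de <- MASS::kde2d(x, y, h = h, n = n_grid,
                        lims = c(lims[[1]], lims[[2]]))
      peak_i <- arrayInd(which.max(de$z), dim(de$z))
      list(grid = list(de$x, de$y), density = de$z,
           peak = stats::setNames(c(de$x[peak_i[1]], de$y[peak_i[2]]),
                                  dims))
    }
  }
  top_k <- kde_set(top)
  bot_k <- kde_set(bottom)

  # back-transform peaks to natural scale and flag boundary proximity
  peak_natural <- function(pk) {
    stats::setNames(vapply(dims, function(d)
      if (d %in% log_dims) 10^pk[[d]] else pk[[d]], 0), dims)
  }
  on_boundary <- function(pk) {
    any(vapply(dims, function(d) {
      r <- lims[[d]]
      (pk[[d]] - r[1]) < 0.05 * diff(r) || (r[2] - pk[[d]]) < 0.05 * diff(r)
    }, TRUE))
  }
  structure(list(
    dims = dims, log_dims = log_dims, quantile_frac = quantile_frac,
    n_records = n, n_quantile = n_q, degenerate = degenerate,
    top = top_k, bottom = bot_k,
    top_peak = peak_natural(top_k$peak),
    bottom_peak = peak_natural(bot_k$peak),
    top_peak_on_boundary = on_boundary(top_k$peak),
    bottom_peak_on_boundary = on_boundary(bot_k$peak),
    bounds = lims), class = "conn_landscape")
}

#' @export
print.conn_landscape <- function(x, ...) {
  cat("Hyperparameter landscape over ", paste(x$dims, collapse = " x "),
      " (", x$n_quantile, " of ", x$n_records, " records per quantile)\n",
      sep = "")
  if (x$degenerate)
    cat("  DEGENERATE: all records have identical performance\n")
  cat("  top-quantile peak:    ",
      paste(x$dims, "=", signif(x$top_peak, 4), collapse = ", "),
      if (x$top_peak_on_boundary) "  [on search boundary]", "\n")
  cat("  bottom-quantile peak: ",
      paste(x$dims, "=", signif(x$bottom_peak, 4), collapse = ", "),
      if (x$bottom_peak_on_boundary) "  [on search boundary]", "\n")
  invisible(x)
}
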