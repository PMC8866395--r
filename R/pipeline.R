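# Orchestration: one configuration object drives cohort simulation,
# feature building, search, importance, landscape and external validation,
# writing plain-text artifacts plus a manifest sufficient to re-execute
# the run bit-identically.

#' Build and validate a pipeline run configuration
#'
#' @param cohort a `cohort_spec` (simulated cohort) or a directory written
#'   by [write_cohort()]
#' @param families model families to search
#' @param feature_sets feature-set modes
#' @param n_configs configurations per (family x feature set)
#' @param seed master seed; per-stage seeds are derived deterministically
#' @param out_dir output directory
#' @param stages subset of c("search", "importance", "landscape",
#'   "external")
#' @param importance_family,importance_set cell interrogated by the
#'   importance stage (default: best test-AUROC cell)
#' @param top_m number of top configurations for the consensus ranking
#' @param n_label_perms label permutations for the importance null
#' @param n_reps permutation repetitions per feature
#' @param external a `cohort_spec` for the external cohort (or NULL to
#'   skip the external stage)
#' @param landscape_dims dims for the landscape stage
#' @return object of class `run_config`
#' @export
run_config <- function(cohort, families = c("logistic_ridge", "dfnn"),
                       feature_sets = "functional", n_configs = 10,
                       seed = 1L, out_dir = tempfile("conndiag_run_"),
                       stages = c("search", "importance", "landscape",
                                  "external"),
                       importance_family = NULL, importance_set = NULL,
                       top_m = 5, n_label_perms = 20, n_reps = 64,
                       external = NULL,
                       landscape_dims = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!inherits(cohort, "cohort_spec") &&
      !(is.character(cohort) && dir.exists(cohort)))
    stop("cohort must be a cohort_spec or an existing cohort directory")
  fams <- model_families()
  bad <- setdiff(families, fams$family)
  if (length(bad)) stop("unknown families: ", paste(bad, collapse = ", "))
  if ("external" %in% stages && !is.null(external) &&
      !inherits(external, "cohort_spec"))
    stop("external must be a cohort_spec or NULL")
  structure(list(cohort = cohort, families = families,
                 feature_sets = feature_sets, n_configs = n_configs,
                 seed = as.integer(seed), out_dir = out_dir,
                 stages = stages,
                 importance_family = importance_family,
                 importance_set = importance_set, top_m = top_m,
                 n_label_perms = n_label_perms, n_reps = n_reps,
                 external = external, landscape_dims = landscape_dims),
            class = "run_config")
}

stage_seed <- function(config, stage) {
  substream_seed(config$seed, match(stage, c("cohort", "split", "search",
                                             "importance", "landscape",
                                             "external")), salt = 404L)
}

#' Execute the pipeline
#'
#' Runs the enabled stages in order (cohort -> features/search ->
#' importance -> landscape -> external), writes every table as CSV under
#' `out_dir`, and finishes with `manifest.json` capturing the
#' configuration, per-stage artifact checksums and wall-clock times.
#'
#' @param config a `run_config`
#' @param verbose narrate stage starts/ends
#' @return the manifest (invisibly also written to
#'   `out_dir/manifest.json`); stage results are attached as the
#'   `results` attribute
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = serialize_config(config),
                   stages = list())
  results <- list()
  tic <- function() Sys.time()
  took <- function(t0) as.numeric(Sys.time() - t0, units = "secs")

  t0 <- tic()
  msg("stage cohort: seed %d", stage_seed(config, "cohort"),
      verbose = verbose)
  cohort <- if (inherits(config$cohort, "cohort_spec")) {
    generate_cohort(config$cohort)
  } else read_cohort(config$cohort)
  y <- cohort_labels(cohort)
  plan <- make_split_plan(y, cohort_sex(cohort),
                          seed = stage_seed(config, "split"))
  write_split_plan(plan, file.path(config$out_dir, "split_plan.json"))
  manifest$stages$cohort <- list(n_subjects = length(y),
                                 plan_checksum = plan$checksum,
                                 seconds = took(t0))
  results$cohort <- cohort
  results$plan <- plan

  search <- NULL
  if ("search" %in% config$stages) {
    t0 <- tic()
    msg("stage search: %d families x %d feature sets x %d configs",
        length(config$families), length(config$feature_sets),
        config$n_configs, verbose = verbose)
    search <- run_search(cohort, config$families, config$feature_sets,
                         n_configs = config$n_configs, plan = plan,
                         seed = stage_seed(config, "search"),
                         journal = file.path(config$out_dir,
                                             "search_records.jsonl"),
                         verbose = verbose)
    utils::write.csv(as.data.frame(search$result_matrix),
                     file.path(config$out_dir, "result_matrix.csv"))
    utils::write.csv(search_records(search),
                     file.path(config$out_dir, "search_table.csv"),
                     row.names = FALSE)
    manifest$stages$search <- list(
      n_records = length(search$records),
      result_checksum = object_checksum(search$result_matrix),
      seconds = took(t0))
    results$search <- search
  }

  if ("importance" %in% config$stages && !is.null(search)) {
    t0 <- tic()
    cell <- pick_importance_cell(search, config$importance_family,
                                 config$importance_set)
    msg("stage importance: %s x %s, top %d configs", cell$family,
        cell$feature_set, config$top_m, verbose = verbose)
    imp_res <- interrogate_cell(search, cohort, cell$family,
                                cell$feature_set, top_m = config$top_m,
                                n_label_perms = config$n_label_perms,
                                n_reps = config$n_reps,
                                seed = stage_seed(config, "importance"))
    utils::write.csv(importance_table(imp_res),
                     file.path(config$out_dir, "importance_table.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(imp_res$consensus),
                     file.path(config$out_dir, "consensus_top.csv"),
                     row.names = FALSE)
    manifest$stages$importance <- list(
      family = cell$family, feature_set = cell$feature_set,
      n_significant = sum(imp_res$median_importance$significant),
      seconds = took(t0))
    results$importance <- imp_res
  } else if ("importance" %in% config$stages) {
    manifest$stages$importance <- list(skipped = "search stage disabled")
  }

  if ("landscape" %in% config$stages && !is.null(search)) {
    t0 <- tic()
    dims <- config$landscape_dims
    fam <- config$importance_family %||%
      pick_importance_cell(search, NULL, NULL)$family
    if (is.null(dims)) {
      sp <- hyperparameter_space(fam)
      dims <- utils::head(names(sp), 2)
    }
    if (length(dims) >= 1) {
      ls <- tryCatch(
        landscape_kde(search, dims = dims, family = fam),
        error = function(e) e)
      if (!inherits(ls, "error")) {
        utils::write.csv(landscape_peaks(ls),
                         file.path(config$out_dir, "landscape_peaks.csv"),
                         row.names = FALSE)
        results$landscape <- ls
        manifest$stages$landscape <- list(dims = dims,
                                          seconds = took(t0))
      } else {
        manifest$stages$landscape <- list(skipped = conditionMessage(ls))
      }
    }
  } else if ("landscape" %in% config$stages) {
    manifest$stages$landscape <- list(skipped = "search stage disabled")
  }

  if ("external" %in% config$stages && !is.null(config$external) &&
      !is.null(search)) {
    t0 <- tic()
    msg("stage external: transfer + adaptation", verbose = verbose)
    cell <- pick_importance_cell(search, config$importance_family,
                                 config$importance_set)
    best <- search$best[[paste(cell$family, cell$feature_set,
                               sep = "::")]]
    ext_cohort <- generate_cohort(config$external)
    fe <- external_features(ext_cohort, cell$feature_set, best$ref,
                            best$scaler, best$site_levels)
    Xe <- fe$X; attr(Xe, "kinds") <- fe$kinds
    ye <- cohort_labels(ext_cohort)
    tr <- transfer_evaluate(list(best$model), Xe, ye, best$ref,
                            best$scaler)
    ad <- domain_adapt(best$model, Xe, ye,
                       seed = stage_seed(config, "external"))
    utils::write.csv(
      data.frame(model = cell$family, transfer_auroc = tr$mean,
                 adapted_auroc = ad$mean, adapted_sd = ad$sd,
                 mode = ad$mode),
      file.path(config$out_dir, "transfer_report.csv"), row.names = FALSE)
    manifest$stages$external <- list(
      transfer_auroc = tr$mean, adapted_auroc = ad$mean,
      seconds = took(t0))
    results$external <- list(transfer = tr, adaptation = ad)
  } else if ("external" %in% config$stages) {
    manifest$stages$external <- list(
      skipped = if (is.null(config$external)) "no external spec"
                else "search stage disabled")
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  attr(manifest, "results") <- results
  invisible(manifest)
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$cohort <- if (inherits(out$cohort, "cohort_spec"))
    unclass(out$cohort) else out$cohort
  out$external <- if (inherits(out$external, "cohort_spec"))
    unclass(out$external) else out$external
  out
}

pick_importance_cell <- function(search, family, feature_set) {
  if (!is.null(family) && !is.null(feature_set))
    return(list(family = family, feature_set = feature_set))
  m <- search$result_matrix
  ij <- arrayInd(which.max(m), dim(m))
  list(family = rownames(m)[ij[1]], feature_set = colnames(m)[ij[2]])
}

#' Interrogate one search cell: top-m configs, PFI, null, consensus
#'
#' Refits the `top_m` configurations (by mean CV AUROC) of one (family x
#' feature set) cell on the full training set, computes permutation
#' feature importance for each on the held-out test rows, attaches
#' significance for the median-ranked model against a label-permutation
#' null, ranks the consensus features, and marks univariate directions.
#'
#' @param search a `conn_search` with kept models
#' @param cohort the cohort the search ran on
#' @param family,feature_set the cell to interrogate
#' @param top_m number of top configurations (default 5)
#' @param top_k consensus list length (default 15)
#' @param n_label_perms,n_reps null and PFI sizes
#' @param seed seed
#' @param feature_kinds which feature kinds enter the consensus ranking
#'   (default: all)
#' @param with_null build the label-permutation null and significance for
#'   the median-ranked model (the expensive part; FALSE skips it)
#' @return list with `importances` (one `conn_importance` per model),
#'   `median_importance` (significance-annotated importance of the
#'   median-ranked model), `null`, `consensus` (with direction marks),
#'   `configs`
#' @export
interrogate_cell <- function(search, cohort, family, feature_set,
                             top_m = 5, top_k = 15, n_label_perms = 20,
                             n_reps = 64, seed = 1L,
                             feature_kinds = NULL, with_null = TRUE) {
  stopifnot(inherits(search, "conn_search"))
  plan <- search$plan
  y <- cohort_labels(cohort)
  cell_recs <- Filter(function(r)
    r$family == family && r$feature_set == feature_set &&
      !isTRUE(r$failed), search$records)
  if (length(cell_recs) < 2) stop("not enough usable records in this cell")
  ord <- order(vapply(cell_recs, `[[`, 0, "mean_cv_auroc"),
               decreasing = TRUE)
  top <- cell_recs[ord[seq_len(min(top_m, length(cell_recs)))]]

  best <- search$best[[paste(family, feature_set, sep = "::")]]
  if (is.null(best)) stop("no kept artifacts for this cell")
  fe <- build_features(cohort, feature_set, fit_idx = plan$train,
                       ref = best$ref, scaler = best$scaler,
                       site_levels = best$site_levels)
  Xtr <- fe$X[plan$train, , drop = FALSE]; attr(Xtr, "kinds") <- fe$kinds
  Xte <- fe$X[plan$test, , drop = FALSE]; attr(Xte, "kinds") <- fe$kinds

  feats <- colnames(Xte)
  if (!is.null(feature_kinds)) feats <- feats[fe$kinds %in% feature_kinds]

  importances <- lapply(seq_along(top), function(i) {
    r <- top[[i]]
    m <- fit_model(family, r$config, Xtr, y[plan$train],
                   seed = r$config_seed)
    permutation_importance(m, Xte, y[plan$test], n_reps = n_reps,
                           seed = substream_seed(seed, i, salt = 55L),
                           features = feats)
  })

  # significance for the median-ranked model of the top set
  med_i <- ord_median_index(length(importances))
  null <- NULL
  median_importance <- importances[[med_i]]
  if (with_null) {
    r_med <- top[[med_i]]
    null <- build_null(family, r_med$config, Xtr, y[plan$train], Xte,
                       y[plan$test], n_label_perms = n_label_perms,
                       n_reps = n_reps,
                       seed = substream_seed(seed, 99L, salt = 55L),
                       features = feats)
    median_importance <- significance(importances[[med_i]], null)
  }

  consensus <- consensus_rank(importances, top_k = top_k)
  dm <- lapply(consensus$feature, function(f)
    direction_mark(Xte, y[plan$test], f))
  consensus$direction <- vapply(dm, `[[`, "", "mark")
  consensus$direction_p <- vapply(dm, `[[`, 0, "p")

  list(importances = importances, median_importance = median_importance,
       null = null, consensus = consensus,
       configs = lapply(top, `[[`, "config"),
       family = family, feature_set = feature_set)
}

ord_median_index <- function(k) as.integer(ceiling(k / 2))

importance_table <- function(imp_res) {
  mi <- imp_res$median_importance
  df <- as.data.frame(mi)
  zmat <- vapply(imp_res$importances, function(im)
    im$z[match(mi$feature, im$feature)], numeric(nrow(mi)))
  colnames(zmat) <- paste0("z_model", seq_len(ncol(zmat)))
  cbind(df, zmat)
}

landscape_peaks <- function(ls) {
  data.frame(quantile = c("top", "bottom"),
             rbind(ls$top_peak, ls$bottom_peak),
             on_boundary = c(ls$top_peak_on_boundary,
                             ls$bottom_peak_on_boundary),
             row.names = NULL)
}

#' Re-render report tables from a finished run directory
#'
#' @param out_dir a directory written by [run_pipeline()]
#' @return character vector of report files present (missing stage outputs
#'   are skipped with a message)
#' @export
render_reports <- function(out_dir) {
  expected <- c("result_matrix.csv", "search_table.csv",
                "importance_table.csv", "consensus_top.csv",
                "landscape_peaks.csv", "transfer_report.csv",
                "split_plan.json", "manifest.json")
  present <- character(0)
  for (f in expected) {
    path <- file.path(out_dir, f)
    if (file.exists(path)) present <- c(present, path)
    else message("report skipped (missing stage output): ", f)
  }
  present
}
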