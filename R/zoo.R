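# The model zoo: twelve classifier families (3 classical linear, 6
# classical nonlinear, 3 neural) behind one training/scoring contract.
# Hyperparameter search spaces live in a JSON registry
# (inst/extdata/model_spaces.json): spaces are data, not code.

.zoo_env <- new.env(parent = emptyenv())

zoo_registry <- function() {
  if (is.null(.zoo_env$registry)) {
    path <- system.file("extdata", "model_spaces.json", package = "conndiag")
    if (path == "") path <- file.path("inst", "extdata", "model_spaces.json")
    .zoo_env$registry <- jsonlite::read_json(path, simplifyVector = FALSE)
  }
  .zoo_env$registry
}

#' The model families of the zoo
#'
#' @return data frame with `family`, `category` (linear/nonlinear/deep) and
#'   `square_input` (TRUE for the connectome CNN, which accepts only
#'   functional connectivity input)
#' @export
model_families <- function() {
  reg <- zoo_registry()
  data.frame(family = names(reg),
             category = vapply(reg, `[[`, "", "category"),
             square_input = vapply(reg, `[[`, TRUE, "square_input"),
             row.names = NULL)
}

#' Hyperparameter search space of one family
#'
#' Ranges follow the published search table. The adaptive-boosting
#' learning-rate range of [5, 50] is kept as printed but is atypical;
#' `adaboost_conventional_lr = TRUE` substitutes the conventional
#' [0.01, 1] log-uniform range.
#'
#' @param family family name
#' @param adaboost_conventional_lr use a conventional learning-rate range
#'   for adaptive boosting instead of the printed one
#' @return named list of dimensions, each with `lo`, `hi`, `scale`, `type`
#' @export
hyperparameter_space <- function(family, adaboost_conventional_lr = FALSE) {
  reg <- zoo_registry()
  if (!family %in% names(reg)) stop("unknown model family: ", family)
  space <- reg[[family]]$space
  if (family == "adaboost" && adaboost_conventional_lr)
    space$learning_rate <- list(lo = 0.01, hi = 1, scale = "log",
                                type = "real")
  space
}

#' Draw one random configuration from a family's search space
#'
#' Each dimension is drawn independently: uniformly on its range, or
#' uniformly on the log of the range for log-scaled dimensions. Integer
#' dimensions are rounded after the draw.
#'
#' @param family family name
#' @param seed integer seed (deterministic draw)
#' @param draw_index recorded index of this draw within a search
#' @param ... passed to [hyperparameter_space()]
#' @return an object of class `model_config`
#' @export
sample_config <- function(family, seed = 1L, draw_index = 1L, ...) {
  space <- hyperparameter_space(family, ...)
  values <- with_seed(seed, {
    lapply(space, function(d) {
      v <- if (identical(d$scale, "log")) {
        exp(stats::runif(1, log(d$lo), log(d$hi)))
      } else stats::runif(1, d$lo, d$hi)
      if (identical(d$type, "integer")) v <- as.integer(round(v))
      v
    })
  })
  structure(list(family = family, values = values,
                 draw_index = as.integer(draw_index),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("Config #", x$draw_index, " for ", x$family, ": ", sep = "")
  if (length(x$values) == 0) cat("(no hyperparameters)")
  else cat(paste(names(x$values),
                 vapply(x$values, format, "", digits = 4), sep = "=",
                 collapse = ", "))
  cat("\n")
  invisible(x)
}

deep_train_defaults <- function() {
  list(lr = 1e-3, batch_size = 32L, max_epochs = 100L, patience = 10L,
       val_frac = 0.1)
}

signature_of <- function(X) object_checksum(colnames(X))

# Orientation of an svm decision value: e1071 labels the column
# "<positive>/<negative>"; we need higher = class 1.
svm_orientation <- function(dec) {
  nm <- colnames(dec)[1] %||% "0/1"
  if (startsWith(nm, "1")) 1 else -1
}

#' Fit one model of the zoo
#'
#' Trains a classifier of the given family with the given configuration.
#' Neural families train with Adam, minibatches, dropout, L2 weight decay
#' and early stopping monitored on `X_val`/`y_val` (or on an internal
#' stratified 10% carve-out when no validation set is supplied); the
#' decision layer has a single unit. Classical families delegate to
#' established implementations. All fits are deterministic given `seed`.
#'
#' @param family family name (see [model_families()])
#' @param config a `model_config` (use [sample_config()]); NULL draws one
#' @param X feature matrix with column names (standardized)
#' @param y binary 0/1 labels, both classes present
#' @param seed fitting seed
#' @param X_val,y_val optional validation data for early stopping (neural
#'   families)
#' @param artifact_checksums optional named list of preprocessing checksums
#'   (tangent reference, scaler) frozen into the model for leakage guards
#' @return an object of class `conn_model`
#' @export
fit_model <- function(family, config = NULL, X, y, seed = 1L,
                      X_val = NULL, y_val = NULL,
                      artifact_checksums = NULL) {
  fams <- model_families()
  if (!family %in% fams$family) stop("unknown model family: ", family)
  if (is.null(config)) config <- sample_config(family, seed = seed)
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (any(!is.finite(X))) stop("X must be finite")
  v <- config$values
  kinds <- attr(X, "kinds")

  fit <- with_seed(substream_seed(seed, 17L, salt = 3L), switch(
    family,
    naive_bayes = {
      keep <- apply(X, 2, stats::sd) > 0
      list(model = e1071::naiveBayes(
             x = as.data.frame(X[, keep, drop = FALSE]),
             y = factor(y, levels = c(0, 1))),
           keep = keep)
    },
    random_forest = {
      randomForest::randomForest(
        x = X, y = factor(y, levels = c(0, 1)),
        ntree = v$estimators, maxnodes = v$max_nodes)
    },
    extra_trees = {
      df <- as.data.frame(X)
      names(df) <- make.names(names(df))
      df$.outcome <- factor(y, levels = c(0, 1))
      ranger::ranger(
        dependent.variable.name = ".outcome", data = df,
        num.trees = v$estimators,
        max.depth = ceiling(log2(v$max_nodes + 1)),
        splitrule = "extratrees", num.random.splits = 1,
        probability = TRUE, num.threads = 1,
        seed = substream_seed(seed, 18L, salt = 3L))
    },
    adaboost = {
      fit_adaboost_stumps(X, y, n_estimators = v$estimators,
                          learning_rate = v$learning_rate)
    },
    gradient_boosting = {
      xgboost::xgboost(
        x = X, y = factor(y, levels = c(0, 1)), nrounds = v$estimators,
        learning_rate = v$learn_rate, max_depth = v$max_depth,
        subsample = v$subsample, colsample_bytree = v$colsample,
        nthreads = 1, seed = substream_seed(seed, 18L, salt = 4L),
        verbosity = 0)
    },
    svm_gaussian = ,
    svm_linear = {
      m <- e1071::svm(
        x = X, y = factor(y, levels = c(0, 1)),
        kernel = if (family == "svm_gaussian") "radial" else "linear",
        cost = v$C,
        gamma = if (family == "svm_gaussian") v$gamma else 1 / ncol(X),
        scale = FALSE)
      dec <- attr(stats::predict(m, X[1:2, , drop = FALSE],
                                 decision.values = TRUE),
                  "decision.values")
      list(model = m, orientation = svm_orientation(dec))
    },
    logistic_lasso = ,
    logistic_ridge = {
      glmnet::glmnet(
        X, y, family = "binomial",
        alpha = if (family == "logistic_lasso") 1 else 0,
        lambda = 1 / (v$C * nrow(X)), maxit = v$max_iter,
        standardize = FALSE)
    },
    dfnn = {
      arch <- mlp_arch(ncol(X), v$hidden_layers, v$initial_width,
                       dropout = v$dropout)
      td <- deep_train_defaults()
      tr <- train_network(arch, X, y, l2 = v$l2, lr = td$lr,
                          batch_size = td$batch_size,
                          max_epochs = td$max_epochs, patience = td$patience,
                          val_input = X_val, val_y = y_val,
                          val_frac = td$val_frac,
                          seed = substream_seed(seed, 19L, salt = 3L))
      list(arch_spec = list(kind = "dfnn", p_in = ncol(X),
                            hidden_layers = v$hidden_layers,
                            initial_width = v$initial_width,
                            dropout = v$dropout, l2 = v$l2),
           params = tr$params, train = tr[c("epochs_run", "best_epoch")])
    },
    lstm = {
      arch <- lstm_arch(ncol(X), v$hidden_layers, v$initial_width,
                        dropout = v$dropout)
      td <- deep_train_defaults()
      tr <- train_network(arch, X, y, l2 = v$l2, lr = td$lr,
                          batch_size = td$batch_size,
                          max_epochs = td$max_epochs, patience = td$patience,
                          val_input = X_val, val_y = y_val,
                          val_frac = td$val_frac,
                          seed = substream_seed(seed, 19L, salt = 3L))
      list(arch_spec = list(kind = "lstm", p_in = ncol(X),
                            hidden_layers = v$hidden_layers,
                            initial_width = v$initial_width,
                            dropout = v$dropout, l2 = v$l2),
           params = tr$params, train = tr[c("epochs_run", "best_epoch")])
    },
    brainnet_cnn = {
      inp <- edges_to_matrices(X, kinds)
      arch <- bncnn_arch(inp$R, ncol(inp$cov), v$hidden_layers,
                         v$initial_width, dropout = v$dropout,
                         slope = v$leaky_slope)
      td <- deep_train_defaults()
      val_inp <- if (!is.null(X_val)) {
        vi <- edges_to_matrices(X_val, attr(X_val, "kinds") %||% kinds)
        list(A = vi$A, cov = vi$cov)
      }
      tr <- train_network(arch, list(A = inp$A, cov = inp$cov), y,
                          l2 = 0, lr = td$lr, batch_size = td$batch_size,
                          max_epochs = td$max_epochs, patience = td$patience,
                          val_input = val_inp, val_y = y_val,
                          val_frac = td$val_frac,
                          seed = substream_seed(seed, 19L, salt = 3L))
      list(arch_spec = list(kind = "brainnet_cnn", R = inp$R,
                            n_cov = ncol(inp$cov),
                            e2e_blocks = v$hidden_layers,
                            width = v$initial_width, dropout = v$dropout,
                            slope = v$leaky_slope),
           params = tr$params, train = tr[c("epochs_run", "best_epoch")])
    },
    stop("unhandled family ", family)))

  structure(list(family = family, config = config, fit = fit,
                 features = colnames(X), signature = signature_of(X),
                 seed = as.integer(seed),
                 artifact_checksums = artifact_checksums,
                 train_meta = if (fams$category[fams$family == family] ==
                                  "deep") deep_train_defaults()),
            class = "conn_model")
}

rebuild_arch <- function(spec) {
  switch(spec$kind,
    dfnn = mlp_arch(spec$p_in, spec$hidden_layers, spec$initial_width,
                    dropout = spec$dropout),
    lstm = lstm_arch(spec$p_in, spec$hidden_layers, spec$initial_width,
                     dropout = spec$dropout),
    brainnet_cnn = bncnn_arch(spec$R, spec$n_cov, spec$e2e_blocks,
                              spec$width, dropout = spec$dropout,
                              slope = spec$slope))
}

#' Continuous classification scores from a fitted model
#'
#' Returns one score per row of `X`, higher meaning more case-like. The
#' feature signature of `X` must match the training signature.
#'
#' @param model a `conn_model`
#' @param X feature matrix
#' @return numeric score vector of length `nrow(X)`
#' @export
predict_score <- function(model, X) {
  stopifnot(inherits(model, "conn_model"), is.matrix(X))
  if (!identical(signature_of(X), model$signature))
    stop("feature signature mismatch: the matrix does not match the ",
         "features this model was trained on")
  v <- model$config$values
  switch(model$family,
    naive_bayes = {
      pr <- stats::predict(model$fit$model,
                           as.data.frame(X[, model$fit$keep, drop = FALSE]),
                           type = "raw")
      as.numeric(pr[, "1"])
    },
    random_forest = {
      as.numeric(stats::predict(model$fit, X, type = "prob")[, "1"])
    },
    extra_trees = {
      df <- as.data.frame(X)
      names(df) <- make.names(names(df))
      as.numeric(stats::predict(model$fit, data = df,
                                num.threads = 1)$predictions[, "1"])
    },
    adaboost = predict_adaboost_stumps(model$fit, X),
    gradient_boosting = as.numeric(stats::predict(model$fit, X)),
    svm_gaussian = ,
    svm_linear = {
      dec <- attr(stats::predict(model$fit$model, X,
                                 decision.values = TRUE),
                  "decision.values")
      model$fit$orientation * as.numeric(dec[, 1])
    },
    logistic_lasso = ,
    logistic_ridge = {
      as.numeric(stats::predict(model$fit, X, type = "link"))
    },
    dfnn = ,
    lstm = {
      arch <- rebuild_arch(model$fit$arch_spec)
      as.numeric(predict_network(arch, model$fit$params, X))
    },
    brainnet_cnn = {
      arch <- rebuild_arch(model$fit$arch_spec)
      inp <- edges_to_matrices(X, attr(X, "kinds"))
      as.numeric(predict_network(arch, model$fit$params,
                                 list(A = inp$A, cov = inp$cov)))
    })
}

#' @export
predict.conn_model <- function(object, newdata, ...) {
  predict_score(object, newdata)
}

#' @export
print.conn_model <- function(x, ...) {
  fams <- model_families()
  cat("conn_model: ", x$family, " (",
      fams$category[fams$family == x$family], "), ",
      length(x$features), " features\n", sep = "")
  print(x$config)
  invisible(x)
}

#' Warm-start fine-tuning of a fitted neural model
#'
#' Continues Adam training of a neural family from its current weights on
#' new data, with early stopping monitored on a stratified sliver of the
#' tuning data. `max_epochs = 0` returns the model unchanged (a no-op
#' adaptation). Classical families have no warm start; see
#' [domain_adapt()], which refits them from scratch and flags this.
#'
#' @param model a deep-family `conn_model`
#' @param X,y tuning data
#' @param max_epochs epoch budget for fine-tuning
#' @param lr fine-tuning learning rate (default: a tenth of the training
#'   rate)
#' @param patience early-stopping patience
#' @param seed seed
#' @return the tuned `conn_model`
#' @export
fine_tune_model <- function(model, X, y, max_epochs = 50, lr = 1e-4,
                            patience = 10, seed = 1L) {
  stopifnot(inherits(model, "conn_model"))
  if (!model$family %in% c("dfnn", "lstm", "brainnet_cnn"))
    stop("warm-start fine-tuning is only defined for the neural families")
  if (!identical(signature_of(X), model$signature))
    stop("feature signature mismatch")
  if (max_epochs == 0) return(model)
  spec <- model$fit$arch_spec
  arch <- rebuild_arch(spec)
  arch$init <- local({p <- model$fit$params; function() p})
  input <- if (model$family == "brainnet_cnn") {
    inp <- edges_to_matrices(X, attr(X, "kinds"))
    list(A = inp$A, cov = inp$cov)
  } else X
  l2 <- model$fit$arch_spec$l2 %||% 0
  tr <- train_network(arch, input, as.integer(y), l2 = l2, lr = lr,
                      batch_size = min(32L, length(y)),
                      max_epochs = max_epochs, patience = patience,
                      val_frac = 0.2,
                      seed = substream_seed(seed, 23L, salt = 3L))
  model$fit$params <- tr$params
  model$fit$train <- tr[c("epochs_run", "best_epoch")]
  model
}
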