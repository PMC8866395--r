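# Frozen stratified split plan: the fairness contract. One plan object is
# built once per experiment and consumed by every model family; its checksum
# is recorded in every search record.

#' Build a frozen stratified train/test + CV-fold plan
#'
#' Splits subjects into a training set (`train_frac`) and a held-out test
#' set with matching proportions of diagnosis and sex in every partition
#' (within one subject per stratum), then assigns the training set to `k`
#' stratified cross-validation folds. Strata with fewer than `k` training
#' subjects trigger a warning and a fallback to diagnosis-only
#' stratification.
#'
#' @param labels binary diagnosis vector
#' @param sex binary sex vector (second stratification variable)
#' @param train_frac training fraction
#' @param k number of CV folds
#' @param seed seed
#' @return an object of class `split_plan` with `train`, `test`, `folds`
#'   (fold id per training subject, aligned with `train`), and `checksum`
#' @export
make_split_plan <- function(labels, sex, train_frac = 0.8, k = 3,
                            seed = 1L) {
  n <- length(labels)
  stopifnot(length(sex) == n, n >= 10 * k)
  strata <- interaction(labels, sex, drop = TRUE)
  if (min(table(strata)) < k) {
    warning("a diagnosis x sex stratum is too small; ",
            "falling back to diagnosis-only stratification")
    strata <- factor(labels)
  }
  test <- integer(0)
  with_seed(substream_seed(seed, 1L, salt = 7L), {
    for (s in levels(strata)) {
      idx <- which(strata == s)
      n_test <- round(length(idx) * (1 - train_frac))
      test <- c(test, sample(idx, n_test))
    }
  })
  test <- sort(test)
  train <- setdiff(seq_len(n), test)
  folds <- integer(length(train))
  with_seed(substream_seed(seed, 2L, salt = 7L), {
    fold_counts <- integer(k)
    for (s in levels(strata)) {
      idx <- which(strata[train] == s)
      base <- length(idx) %/% k
      rem <- length(idx) %% k
      # give remainders to the currently smallest folds so that overall
      # fold sizes differ by at most one
      lab <- c(rep(seq_len(k), base), order(fold_counts)[seq_len(rem)])
      folds[sample(idx)] <- lab
      fold_counts <- fold_counts + tabulate(lab, k)
    }
  })
  plan <- structure(list(train = train, test = test, folds = folds, k = k,
                         train_frac = train_frac, seed = as.integer(seed),
                         n = n),
                    class = "split_plan")
  plan$checksum <- object_checksum(plan[c("train", "test", "folds")])
  plan
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Split plan: ", length(x$train), " train / ", length(x$test),
      " test, k = ", x$k, " folds (seed ", x$seed, ")\n", sep = "")
  cat("  checksum:", x$checksum, "\n")
  invisible(x)
}

#' Serialize / restore a split plan as JSON
#' @param plan a `split_plan`
#' @param path file path
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan)[c("train", "test", "folds", "k",
                                       "train_frac", "seed", "n")],
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan <- structure(list(train = as.integer(j$train),
                         test = as.integer(j$test),
                         folds = as.integer(j$folds), k = j$k,
                         train_frac = j$train_frac,
                         seed = as.integer(j$seed), n = j$n),
                    class = "split_plan")
  plan$checksum <- object_checksum(plan[c("train", "test", "folds")])
  plan
}
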