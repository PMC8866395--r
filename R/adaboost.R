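# Discrete AdaBoost with decision stumps (depth-1 thresholds), vectorized
# over candidate thresholds via weighted cumulative sums. The learning-rate
# factor scales the per-round stump weight, matching the convention where
# alpha_t = lr * 0.5 * log((1 - err) / err).

fit_adaboost_stumps <- function(X, y, n_estimators, learning_rate = 1) {
  n <- nrow(X); p <- ncol(X)
  y2 <- ifelse(y == 1L, 1, -1)
  ords <- lapply(seq_len(p), function(j) order(X[, j]))
  xs <- lapply(seq_len(p), function(j) X[ords[[j]], j])
  # valid threshold positions: between distinct consecutive sorted values
  valid <- lapply(xs, function(v) which(diff(v) > 0))
  w <- rep(1 / n, n)
  stumps <- vector("list", n_estimators)
  n_used <- 0L
  for (t in seq_len(n_estimators)) {
    best <- list(err = Inf)
    for (j in seq_len(p)) {
      vk <- valid[[j]]
      if (length(vk) == 0) next
      wo <- w[ords[[j]]]
      yo <- y2[ords[[j]]]
      cum_pos <- cumsum(wo * (yo > 0))  # weight of positives with x <= thr
      cum_neg <- cumsum(wo * (yo < 0))
      tot_neg <- cum_neg[n]
      # polarity +1: predict +1 when x > thr
      err_plus <- cum_pos[vk] + (tot_neg - cum_neg[vk])
      err_best_j <- pmin(err_plus, 1 - err_plus)
      kbest <- which.min(err_best_j)
      if (err_best_j[kbest] < best$err) {
        k <- vk[kbest]
        best <- list(err = err_best_j[kbest], feature = j,
                     threshold = (xs[[j]][k] + xs[[j]][k + 1]) / 2,
                     polarity = if (err_plus[kbest] <= 1 - err_plus[kbest])
                       1 else -1)
      }
    }
    if (!is.finite(best$err)) break
    e <- min(max(best$err, 1e-10), 1 - 1e-10)
    alpha <- learning_rate * 0.5 * log((1 - e) / e)
    pred <- best$polarity * ifelse(X[, best$feature] > best$threshold, 1, -1)
    stumps[[t]] <- list(feature = best$feature, threshold = best$threshold,
                        polarity = best$polarity, alpha = alpha)
    n_used <- t
    if (best$err < 1e-10) break
    w <- w * exp(-alpha * y2 * pred)
    w <- w / sum(w)
  }
  list(stumps = stumps[seq_len(n_used)], features = colnames(X))
}

predict_adaboost_stumps <- function(fit, X) {
  score <- numeric(nrow(X))
  for (s in fit$stumps)
    score <- score + s$alpha * s$polarity *
      ifelse(X[, s$feature] > s$threshold, 1, -1)
  score
}
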