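# Ranking metrics.

#' Area under the ROC curve
#'
#' Equals the probability that a uniformly chosen positive outscores a
#' uniformly chosen negative, with ties counted one half (Mann-Whitney
#' form, computed via midranks).
#'
#' @param scores continuous scores, higher = more case-like
#' @param labels binary 0/1 labels
#' @return AUROC in [0, 1]
#' @export
compute_auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity at a target specificity
#'
#' Chooses the decision threshold as the smallest score cutoff achieving
#' specificity at least `specificity` (predict positive when score >
#' threshold) and returns the sensitivity there.
#'
#' @param scores continuous scores, higher = more case-like
#' @param labels binary 0/1 labels
#' @param specificity target specificity in (0, 1]
#' @return sensitivity fraction at the chosen threshold
#' @export
sensitivity_at_specificity <- function(scores, labels, specificity = 0.80) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  th <- sort(unique(scores))
  # candidate thresholds: each unique score (predict positive if score > t)
  spec <- vapply(th, function(t) mean(scores[labels == 0L] <= t), 0)
  ok <- which(spec >= specificity)
  if (length(ok) == 0L) stop("target specificity unreachable")
  t_star <- th[min(ok)]
  mean(scores[labels == 1L] > t_star)
}
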