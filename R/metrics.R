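#' Area under the precision-recall curve
#'
#' Average-precision form of the PR-AUC: precision is evaluated at every
#' distinct score threshold (descending) and integrated against the recall
#' increments, which handles tied scores without interpolation optimism. For
#' an uninformative scorer the expected value equals the positive-class
#' prevalence.
#'
#' @param scores numeric prediction scores, higher = more positive.
#' @param labels logical (or 0/1) vector of true positives.
#' @return PR-AUC in \code{[0, 1]}.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), any(labels))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(!l)
  # threshold boundaries: last index of each run of equal scores
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / sum(l)
  sum(diff(c(0, rec)) * prec)
}

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds so that every fold holds
#' (up to rounding) the same class proportions.
#'
#' @param y factor of class labels.
#' @param k number of folds.
#' @param seed RNG seed for the shuffle.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k, seed) {
  stopifnot(k >= 2, length(y) >= k)
  fold <- integer(length(y))
  rng <- local({ set.seed(seed); lapply(split(seq_along(y), y), sample) })
  for (idx in rng) {
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Classification metrics at a fixed probability threshold
#'
#' @param prob positive-class probabilities.
#' @param truth logical vector of true positives.
#' @param threshold decision threshold (default 0.5).
#' @return named vector `precision`, `recall`, `specificity` (`precision` is
#'   NA when nothing is predicted positive).
#' @keywords internal
threshold_metrics <- function(prob, truth, threshold = 0.5) {
  pred <- prob >= threshold
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = tp / (tp + fn),
    specificity = tn / (tn + fp))
}

#' Welch's unequal-variance t-test between two samples
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = FALSE`
#' (Welch-Satterthwaite degrees of freedom), returning the pieces the
#' comparison tables need.
#'
#' @param x,y numeric samples (length >= 2 each).
#' @return list `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                mean_x = mean(x), mean_y = mean(y)))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_x = mean(x), mean_y = mean(y))
}
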