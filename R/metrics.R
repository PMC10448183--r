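#' Balanced accuracy from sensitivity and specificity
#'
#' The arithmetic mean of sensitivity and specificity; the identity used for
#' every per-split metric set.
#'
#' @param sensitivity,specificity values in `[0, 1]`.
#' @return `(sensitivity + specificity) / 2`.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' Area under the ROC curve
#'
#' Rank (trapezoidal) AUC of scores for a binary outcome: the probability
#' that a random positive outscores a random negative, ties counting one
#' half. Positive class is `ARMS` / the last factor level / 1.
#'
#' @param labels binary labels.
#' @param scores numeric scores, larger = more ARMS-like.
#' @return AUC in `[0, 1]`; `NA` if only one class is present.
#' @export
roc_auc <- function(labels, scores) {
  y <- .labels01(labels, length(scores))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' @inheritParams roc_auc
#' @return data.frame `fpr`, `tpr`, starting at (0,0) and ending at (1,1).
#' @export
roc_curve <- function(labels, scores) {
  y <- .labels01(labels, length(scores))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  keep <- c(diff(ss) != 0, TRUE)   # last index of each distinct score
  tpr <- cumsum(ys)[keep] / max(n1, 1L)
  fpr <- cumsum(1 - ys)[keep] / max(n0, 1L)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Classification metrics at a decision threshold
#'
#' The five evaluation metrics: sensitivity (recall of ARMS), specificity,
#' F1 score (harmonic mean of precision and sensitivity), balanced accuracy
#' (arithmetic mean of sensitivity and specificity) and rank ROC-AUC.
#' Class ARMS is called when `score > threshold`.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold on the score (default 0.5).
#' @return named list `f1`, `specificity`, `sensitivity`,
#'   `balanced_accuracy`, `roc_auc`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  y <- .labels01(labels, length(scores))
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0L) 2 * tp / (2 * tp + fp + fn) else NA_real_
  list(f1 = f1, specificity = spec, sensitivity = sens,
       balanced_accuracy = balanced_accuracy(sens, spec),
       roc_auc = roc_auc(y, scores))
}

#' Vertically averaged ROC curve
#'
#' Interpolates each split's ROC onto a fixed 101-point false-positive-rate
#' grid and returns the pointwise mean and standard deviation of the true
#' positive rate.
#'
#' @param curves list of data.frames with `fpr`, `tpr` (from
#'   [roc_curve()]).
#' @return data.frame `fpr`, `tpr_mean`, `tpr_sd`.
#' @export
mean_roc_curve <- function(curves) {
  stopifnot(length(curves) >= 1L)
  grid <- seq(0, 1, length.out = 101L)
  tprs <- vapply(curves, function(cv) {
    # collapse vertical segments to their top before interpolating; the
    # origin is pinned at (0, 0) so every averaged curve starts there
    top <- aggregate(tpr ~ fpr, data = cv, FUN = max)
    y <- approx(c(0, top$fpr, 1), c(0, top$tpr, 1), xout = grid,
                ties = max)$y
    y[1] <- 0
    y
  }, numeric(length(grid)))
  sds <- apply(tprs, 1L, sd)
  if (length(curves) == 1L) sds <- rep(0, length(grid))
  data.frame(fpr = grid, tpr_mean = rowMeans(tprs), tpr_sd = sds)
}
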