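# ROC curves, trapezoidal AUC and Youden operating points.

#' Receiver operating characteristic curve
#'
#' Sweeps a decision threshold over all distinct score values (ties
#' collapse to a single step, equivalent to half-credit in the
#' Mann-Whitney identity `AUC = U / (n1 * n0)`) and computes the
#' (FPR, TPR) curve and its trapezoidal area.
#'
#' @param scores numeric scores; larger means more PD-like.
#' @param labels class labels: logical, 0/1, or anything equal to
#'   `positive` for the positive class.
#' @param positive value of `labels` taken as the positive (PD) class
#'   when `labels` is not logical/0-1.
#' @return A `tremor_roc` object: data frame `curve` with columns
#'   `threshold`, `fpr`, `tpr` (starting at (0, 0) and ending at
#'   (1, 1)), plus `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, positive = "PD") {
  y <- as_binary_labels(labels, positive)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to build a ROC curve")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  # one step per distinct score value (tie grouping)
  last_of_group <- c(diff(s) != 0, TRUE)
  tpr <- cumsum(yy)[last_of_group] / n_pos
  fpr <- cumsum(1 - yy)[last_of_group] / n_neg
  thr <- s[last_of_group]
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "tremor_roc")
}

as_binary_labels <- function(labels, positive) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    return(as.integer(labels))
  }
  as.integer(as.character(labels) == positive)
}

#' Area under a ROC curve
#' @param x a `tremor_roc` object.
#' @return The trapezoidal AUC in `[0, 1]`.
#' @export
auc <- function(x) {
  stopifnot(inherits(x, "tremor_roc"))
  x$auc
}

#' @export
print.tremor_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives vs %d negatives, AUC = %.3f\n",
              x$n_pos, x$n_neg, x$auc))
  op <- operating_point(x)
  cat(sprintf("Youden operating point: sensitivity %.2f, specificity %.2f",
              op["sensitivity"], op["specificity"]),
      sprintf("at threshold %.4g\n", op["threshold"]))
  invisible(x)
}

#' @export
plot.tremor_roc <- function(x, add = FALSE, col = "black", lwd = 2, ...) {
  if (!add) {
    graphics::plot(x$curve$fpr, x$curve$tpr, type = "l", col = col,
                   lwd = lwd, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "False positive rate (1 - specificity)",
                   ylab = "True positive rate (sensitivity)", ...)
    graphics::abline(0, 1, lty = 3, col = "grey50")
  } else {
    graphics::lines(x$curve$fpr, x$curve$tpr, col = col, lwd = lwd, ...)
  }
  invisible(x)
}

#' Youden-optimal operating point of a ROC curve
#'
#' Picks the curve point maximising Youden's
#' `J = sensitivity + specificity - 1`; ties are broken toward higher
#' sensitivity.
#'
#' @param roc a `tremor_roc` object.
#' @return Named numeric vector `sensitivity`, `specificity`,
#'   `threshold`.
#' @export
operating_point <- function(roc) {
  stopifnot(inherits(roc, "tremor_roc"))
  cv <- roc$curve
  j <- cv$tpr - cv$fpr
  best <- which(j == max(j))
  best <- best[which.max(cv$tpr[best])]
  c(sensitivity = cv$tpr[best], specificity = 1 - cv$fpr[best],
    threshold = cv$threshold[best])
}
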