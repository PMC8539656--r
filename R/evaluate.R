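# Classifier evaluation --------------------------------------------------------

#' Evaluate binary classification scores
#'
#' Computes the confusion counts at a fixed score threshold together with
#' accuracy, precision = TP / (TP + FP), recall = TP / (TP + FN), the area
#' under the ROC curve (via the rank statistic, i.e. the probability a
#' random positive outscores a random negative, ties counted half), and the
#' area under the precision-recall curve by step interpolation over the
#' distinct score thresholds. With a single-class truth vector the
#' threshold-based quantities are still computed where defined and AUC/APR
#' are reported as `NA`.
#'
#' @param y_true 0/1 (or logical) truth vector.
#' @param y_score Numeric scores, same length; higher = more positive.
#' @param threshold Score threshold for the confusion counts (default 0.5;
#'   scores `>= threshold` count as predicted positive).
#' @return An `eval_report` list: `accuracy`, `auc_roc`, `precision`,
#'   `recall`, `apr`, `tp`, `fp`, `tn`, `fn`, `threshold`, `n`. The truth
#'   and score vectors are retained (attributes) for curve plotting.
#' @export
#' @examples
#' evaluate(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))
evaluate <- function(y_true, y_score, threshold = 0.5) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(y_score)) {
    abort("`y_true` and `y_score` must have equal lengths")
  }
  pred <- as.integer(y_score >= threshold)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  tn <- sum(pred == 0 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)

  auc <- if (n1 > 0 && n0 > 0) {
    r <- rank(y_score)
    (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else {
    NA_real_
  }
  apr <- if (n1 > 0 && n0 > 0) {
    ord <- order(y_score, decreasing = TRUE)
    yt <- y_true[ord]; ys <- y_score[ord]
    last <- which(!duplicated(ys, fromLast = TRUE))  # end of each tie group
    tp_cum <- cumsum(yt)[last]
    pp_cum <- last
    rec <- tp_cum / n1
    prec <- tp_cum / pp_cum
    sum(diff(c(0, rec)) * prec)
  } else {
    NA_real_
  }
  structure(
    list(
      accuracy = (tp + tn) / length(y_true),
      auc_roc = auc,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      apr = apr,
      tp = tp, fp = fp, tn = tn, fn = fn,
      threshold = threshold, n = length(y_true)
    ),
    class = "eval_report",
    y_true = y_true, y_score = y_score
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d  accuracy=%.3f  AUC=%.3f  precision=%.3f  recall=%.3f  APR=%.3f\n",
    x$n, x$accuracy, x$auc_roc, x$precision, x$recall, x$apr))
  invisible(x)
}

#' @rdname tidy.gero_classifier
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, auc_roc = x$auc_roc, precision = x$precision,
         recall = x$recall, apr = x$apr, tp = x$tp, fp = x$fp, tn = x$tn,
         fn = x$fn, threshold = x$threshold, n = x$n)
}

# recall/precision and FPR/TPR step curves from the stored scores
eval_curves <- function(report) {
  y <- attr(report, "y_true"); s <- attr(report, "y_score")
  ord <- order(s, decreasing = TRUE)
  yt <- y[ord]; ss <- s[ord]
  last <- which(!duplicated(ss, fromLast = TRUE))
  tp <- cumsum(yt)[last]; pp <- last
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  tibble(
    recall = tp / n1, precision = tp / pp,
    fpr = (pp - tp) / n0, tpr = tp / n1
  )
}

#' Plot precision-recall and ROC curves of an evaluation
#'
#' @param object An `eval_report`.
#' @param type `"pr"` (default) or `"roc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, type = c("pr", "roc"), ...) {
  type <- match.arg(type)
  cv <- eval_curves(object)
  if (type == "pr") {
    ggplot2::ggplot(cv, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(title = sprintf("Precision-recall curve (APR = %.3f)", object$apr),
                    x = "Recall", y = "Precision") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(cv, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
      ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(title = sprintf("ROC curve (AUC = %.3f)", object$auc_roc),
                    x = "False positive rate", y = "True positive rate") +
      ggplot2::theme_minimal()
  }
}
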