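# Diagnostic classification statistics: ROC curves with Mann-Whitney-
# consistent tie handling, trapezoidal AUC, Youden-index binarization,
# confusion-matrix summaries, and the two-point AUC identity for binary
# raters.

#' ROC curve for PD-vs-HC classification
#'
#' Builds the ROC curve with one vertex per distinct score (ties grouped, so
#' the trapezoidal AUC equals the Mann-Whitney statistic with half-credit for
#' ties). With \code{orientation = "lower_is_positive"} a score at or below
#' the cutoff is called PD-positive (the convention for volumes and the
#' composite, which are smaller in PD); with \code{"higher_is_positive"} a
#' score at or above the cutoff is positive.
#'
#' @param scores numeric scores, one per subject.
#' @param labels class labels; \code{positive} identifies the positive (PD)
#'   class.
#' @param orientation \code{"lower_is_positive"} or
#'   \code{"higher_is_positive"}.
#' @param positive label of the positive class (default "PD").
#' @return object of class \code{roc_curve}: data.frame-backed list with
#'   \code{fpr}, \code{tpr} (from (0,0) to (1,1)), \code{thresholds} (the
#'   score cutoff realizing each vertex; -Inf/Inf endpoints), and counts.
#' @export
roc_curve <- function(scores, labels,
                      orientation = c("lower_is_positive", "higher_is_positive"),
                      positive = "PD") {
  orientation <- match.arg(orientation)
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("one class absent: need both PD and HC")
  s <- if (orientation == "lower_is_positive") -scores else scores
  # descending distinct values of s: predicting positive at s >= v
  ord <- order(s, decreasing = TRUE)
  sv <- s[ord]; pv <- pos[ord]
  uq <- unique(sv)
  tp <- cumsum(pv); fp <- cumsum(!pv)
  last_idx <- vapply(uq, function(v) max(which(sv == v)), 0L)
  tpr <- c(0, tp[last_idx] / n1)
  fpr <- c(0, fp[last_idx] / n0)
  thr_internal <- c(Inf, uq)
  thresholds <- if (orientation == "lower_is_positive") -thr_internal else thr_internal
  structure(list(fpr = fpr, tpr = tpr, thresholds = thresholds,
                 orientation = orientation, n_pos = n1, n_neg = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d points, %d positive / %d negative, AUC = %.3f (%s)\n",
              length(x$fpr), x$n_pos, x$n_neg, auc_trapezoid(x), x$orientation))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Trapezoidal AUC
#'
#' Trapezoidal integral of the ROC curve. With ties grouped per distinct
#' score, this equals the Mann-Whitney statistic \code{U / (n1 n2)} with
#' half-credit for ties.
#'
#' @param curve a \code{\link{roc_curve}}.
#' @return AUC in [0, 1].
#' @export
auc_trapezoid <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' Youden-index optimal cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 = tpr - fpr over the curve's
#' vertices; ties are broken toward higher sensitivity.
#'
#' @param curve a \code{\link{roc_curve}}.
#' @return list with \code{cutoff} (score units, orientation-consistent:
#'   predict positive at score <= cutoff for lower_is_positive), \code{J},
#'   \code{sensitivity} and \code{specificity} (proportions).
#' @export
youden_optimal_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  J <- curve$tpr - curve$fpr
  jmax <- max(J)
  cand <- which(J >= jmax - 1e-12)
  best <- cand[which.max(curve$tpr[cand])]
  list(cutoff = curve$thresholds[best], J = J[best],
       sensitivity = curve$tpr[best], specificity = 1 - curve$fpr[best])
}

#' Apply a cutoff to scores and summarize the confusion matrix
#'
#' @param scores,labels as in \code{\link{roc_curve}}.
#' @param cutoff score cutoff.
#' @param orientation as in \code{\link{roc_curve}}.
#' @param positive positive-class label.
#' @return a \code{\link{confusion_summary}}.
#' @export
classify_at_cutoff <- function(scores, labels, cutoff,
                               orientation = c("lower_is_positive",
                                               "higher_is_positive"),
                               positive = "PD") {
  orientation <- match.arg(orientation)
  pred <- if (orientation == "lower_is_positive") scores <= cutoff
          else scores >= cutoff
  pos <- labels == positive
  confusion_summary(tp = sum(pred & pos), fn = sum(!pred & pos),
                    tn = sum(!pred & !pos), fp = sum(pred & !pos))
}

#' Confusion-matrix summary
#'
#' Sensitivity, specificity and accuracy as percentages; Youden J as a
#' proportion.
#'
#' @param tp,fn,tn,fp nonnegative counts.
#' @return object of class \code{classification_summary}: list with
#'   \code{counts}, \code{sensitivity}, \code{specificity}, \code{accuracy}
#'   (percent) and \code{youden}.
#' @export
confusion_summary <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (tp + fn == 0) stop("empty positive class")
  if (tn + fp == 0) stop("empty negative class")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(counts = counts,
                 sensitivity = 100 * sens, specificity = 100 * spec,
                 accuracy = 100 * (tp + tn) / sum(counts),
                 youden = sens + spec - 1),
            class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, digits = 2, ...) {
  cat(sprintf("sensitivity %.*f%%, specificity %.*f%%, accuracy %.*f%%, Youden J %.2f\n",
              digits, x$sensitivity, digits, x$specificity, digits,
              x$accuracy, x$youden))
  cat(sprintf("counts: tp %d, fn %d, tn %d, fp %d\n",
              x$counts["tp"], x$counts["fn"], x$counts["tn"], x$counts["fp"]))
  invisible(x)
}

#' Reconstruct confusion counts from printed rates
#'
#' Recovers the integer confusion matrix from reported sensitivity and
#' specificity percentages and the group sizes, then recomputes all derived
#' metrics.
#'
#' @param sensitivity_pct,specificity_pct percentages in [0, 100].
#' @param n_pos,n_neg group sizes.
#' @return a \code{\link{confusion_summary}}.
#' @export
confusion_from_rates <- function(sensitivity_pct, specificity_pct, n_pos, n_neg) {
  tp <- round(sensitivity_pct / 100 * n_pos)
  tn <- round(specificity_pct / 100 * n_neg)
  confusion_summary(tp = tp, fn = n_pos - tp, tn = tn, fp = n_neg - tn)
}

#' AUC of a binary rater
#'
#' Trapezoidal AUC of the two-point ROC curve through (1 - specificity,
#' sensitivity): \code{(sensitivity + specificity) / 200}.
#'
#' @param sensitivity_pct,specificity_pct percentages in [0, 100].
#' @return AUC in [0, 1].
#' @export
binary_rating_auc <- function(sensitivity_pct, specificity_pct) {
  if (sensitivity_pct < 0 || sensitivity_pct > 100 ||
      specificity_pct < 0 || specificity_pct > 100)
    stop("domain error: rates must be percentages in [0, 100]")
  (sensitivity_pct + specificity_pct) / 200
}

#' Full continuous-marker classification summary
#'
#' ROC + AUC + Youden cutoff + confusion metrics at the cutoff, in one call.
#'
#' @inheritParams roc_curve
#' @return list with \code{auc}, \code{cutoff}, \code{youden}, and the
#'   percent metrics of the \code{\link{classification_summary}} at the
#'   Youden cutoff.
#' @export
classify_measure <- function(scores, labels,
                             orientation = "lower_is_positive",
                             positive = "PD") {
  rc <- roc_curve(scores, labels, orientation, positive)
  yc <- youden_optimal_cutoff(rc)
  cs <- classify_at_cutoff(scores, labels, yc$cutoff, orientation, positive)
  list(auc = auc_trapezoid(rc), cutoff = yc$cutoff, youden = cs$youden,
       accuracy = cs$accuracy, sensitivity = cs$sensitivity,
       specificity = cs$specificity, counts = cs$counts, roc = rc)
}
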