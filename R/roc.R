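# ROC curves, AUC (tie-corrected Mann-Whitney), Youden operating points and
# confusion metrics.  Prediction-positive convention everywhere: score >=
# threshold.

#' ROC curve and AUC
#'
#' The AUC is the tie-corrected Mann-Whitney statistic (probability that a
#' random positive outscores a random negative, ties counted half), computed
#' from midranks.  The curve runs from (0,0) at threshold `+Inf` to (1,1) at
#' the smallest score, thresholds decreasing.
#'
#' @param scores numeric risk scores (higher = riskier).
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return a `rert_roc`: `thresholds`, `tpr`, `fpr`, `n_pos`, `n_neg`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || anyNA(labels)) {
    stop("scores and labels must be complete", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (!all(labels %in% 0:1)) stop("labels must be 0/1", call. = FALSE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n_neg, 0)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr,
                 n_pos = n_pos, n_neg = n_neg, auc = auc),
            class = "rert_roc")
}

#' @export
print.rert_roc <- function(x, ...) {
  cat(sprintf("<rert_roc> AUC = %.4f (%d pos / %d neg, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' Youden-index optimal threshold
#'
#' Maximizes `J = sensitivity + specificity - 1` over candidate thresholds
#' (midpoints between consecutive distinct scores, plus `-Inf`/`+Inf`
#' sentinels).  Ties go to the smallest threshold, favoring sensitivity.
#'
#' @param scores,labels as in [roc_auc()].
#' @return list with `threshold` and `j`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("Youden index undefined: both classes must be present",
         call. = FALSE)
  }
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  j <- vapply(cand, function(t) {
    sum(scores >= t & labels == 1) / n_pos +
      sum(scores < t & labels == 0) / n_neg - 1
  }, 0)
  best <- which(j >= max(j) - 1e-12)[1] # candidates ascending: smallest wins
  list(threshold = cand[best], j = j[best])
}

#' Confusion metrics at a fixed threshold
#'
#' Calls a prediction positive when `score >= threshold` and reports the
#' Youden-point row set: sensitivity, specificity, accuracy, PPV, NPV.
#' Ratios with zero denominators are returned as `NaN` and flagged.
#'
#' @param scores,labels as in [roc_auc()].
#' @param threshold operating threshold.
#' @return a `rert_metrics` list: `auc`, `threshold`, `sensitivity`,
#'   `specificity`, `accuracy`, `ppv`, `npv`, the confusion counts and an
#'   `undefined` character vector naming any flagged ratios.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pos <- scores >= threshold
  tp <- sum(pos & labels == 1)
  fp <- sum(pos & labels == 0)
  tn <- sum(!pos & labels == 0)
  fn <- sum(!pos & labels == 1)
  ratio <- function(a, b) if (b == 0) NaN else a / b
  out <- list(
    auc = roc_auc(scores, labels)$auc,
    threshold = threshold,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    accuracy = (tp + tn) / length(labels),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    tp = tp, fp = fp, tn = tn, fn = fn)
  out$undefined <- names(which(vapply(
    out[c("sensitivity", "specificity", "ppv", "npv")], is.nan, TRUE)))
  structure(out, class = "rert_metrics")
}

#' Metrics at the Youden-optimal threshold
#'
#' Convenience wrapper: finds the Youden threshold and evaluates
#' [confusion_metrics()] there — the standard performance row
#' (AUC, threshold, specificity, sensitivity, accuracy, PPV, NPV).
#'
#' @param scores,labels as in [roc_auc()].
#' @return a `rert_metrics`.
#' @export
metrics_report <- function(scores, labels) {
  yt <- youden_threshold(scores, labels)
  m <- confusion_metrics(scores, labels, yt$threshold)
  m$j <- yt$j
  m
}

#' @export
print.rert_metrics <- function(x, ...) {
  cat("<rert_metrics>\n")
  cat(sprintf("  ROC-AUC                  %.4f\n", x$auc))
  cat(sprintf("  Threshold (Youden Index) %s\n",
              format(x$threshold, digits = 4)))
  cat(sprintf("  Specificity              %.4f\n", x$specificity))
  cat(sprintf("  Sensitivity              %.4f\n", x$sensitivity))
  cat(sprintf("  Accuracy                 %.4f\n", x$accuracy))
  cat(sprintf("  PPV                      %.4f\n", x$ppv))
  cat(sprintf("  NPV                      %.4f\n", x$npv))
  if (length(x$undefined)) {
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}
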