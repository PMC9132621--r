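#' Binary confusion counts
#'
#' @param yTrue,yPred equal-length binary label vectors over the same two
#'   classes.
#' @param positive the class counted as positive; defaults to `"female"`
#'   when present among the labels (the convention used for the recall
#'   headline of the reference pipeline), else the first factor level.
#' @return list with integer `tp`, `tn`, `fp`, `fn` and the `positive` level.
#' @export
confusionCounts <- function(yTrue, yPred, positive = NULL) {
  yTrue <- as.character(yTrue)
  yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred))
    stop("label vectors must have equal length", call. = FALSE)
  lev <- sort(unique(yTrue))
  if (length(lev) > 2L)
    stop("binary labels required", call. = FALSE)
  if (!all(yPred %in% lev))
    stop("predicted label outside the observed binary set", call. = FALSE)
  if (is.null(positive))
    positive <- if ("female" %in% lev) "female" else lev[1L]
  if (!positive %in% lev)
    stop("positive class '", positive, "' not among the labels",
         call. = FALSE)
  tp <- sum(yTrue == positive & yPred == positive)
  tn <- sum(yTrue != positive & yPred != positive)
  fp <- sum(yTrue != positive & yPred == positive)
  fn <- sum(yTrue == positive & yPred != positive)
  list(tp = tp, tn = tn, fp = fp, fn = fn, positive = positive)
}

#' Scalar metrics from confusion counts
#'
#' accuracy = (tp+tn)/(tp+tn+fp+fn), precision = tp/(tp+fp),
#' recall = tp/(tp+fn), F1 = harmonic mean of precision and recall; all
#' reported as percentages. Zero denominators yield 0 with a warning.
#'
#' @param cm output of [confusionCounts()].
#' @return named numeric: `accuracy`, `precision`, `recall`, `f1` (percent).
#' @export
summarizeConfusion <- function(cm) {
  tot <- cm$tp + cm$tn + cm$fp + cm$fn
  if (tot == 0) stop("empty confusion counts", call. = FALSE)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  acc <- (cm$tp + cm$tn) / tot
  prec <- safe(cm$tp, cm$tp + cm$fp, "precision")
  rec <- safe(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- if (prec + rec == 0) {
    warning("zero denominator for F1; reporting 0", call. = FALSE)
    0
  } else 2 * prec * rec / (prec + rec)
  c(accuracy = 100 * acc, precision = 100 * prec, recall = 100 * rec,
    f1 = 100 * f1)
}

#' Harmonic-mean F1 from precision and recall percentages
#'
#' @param precision,recall percentages.
#' @return F1 percentage.
#' @export
f1Score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (ties step simultaneously) with
#' trapezoidal area, computed by [pROC::roc()] with the direction pinned so
#' that larger scores indicate the positive class.
#'
#' @param yTrue binary labels.
#' @param scores finite numeric scores, larger = more positive.
#' @param positive positive class (same default as [confusionCounts()]).
#' @return list with `roc` (data.frame of fpr, tpr, ascending fpr) and `auc`.
#' @export
rocAuc <- function(yTrue, scores, positive = NULL) {
  yTrue <- as.character(yTrue)
  if (!all(is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  lev <- sort(unique(yTrue))
  if (length(lev) != 2L)
    stop("both classes must be present for ROC analysis", call. = FALSE)
  if (is.null(positive))
    positive <- if ("female" %in% lev) "female" else lev[1L]
  negative <- setdiff(lev, positive)
  r <- pROC::roc(response = factor(yTrue, levels = c(negative, positive)),
                 predictor = scores, levels = c(negative, positive),
                 direction = "<", quiet = TRUE)
  df <- data.frame(fpr = rev(1 - r$specificities),
                   tpr = rev(r$sensitivities))
  list(roc = df, auc = as.numeric(pROC::auc(r)))
}

#' Full evaluation report from a cross-validation run
#'
#' Pools the per-fold predictions into one confusion matrix (the headline),
#' computes positive-class, per-class and macro-averaged metrics, per-fold
#' accuracies, and the ROC curve/AUC from the continuous scores.
#'
#' @param cv a [CVResult-class] (or a data.frame with columns `truth`,
#'   `predicted`, `score`, `fold`).
#' @param positive positive class (default `"female"` when present).
#' @return an [EvalReport-class].
#' @export
evalReport <- function(cv, positive = NULL) {
  family <- "classifier"
  if (is(cv, "CVResult")) {
    family <- cv@family
    pred <- cv@predictions
  } else pred <- cv
  cm <- confusionCounts(pred$truth, pred$predicted, positive)
  metrics <- summarizeConfusion(cm)
  lev <- sort(unique(as.character(pred$truth)))
  perClass <- t(vapply(lev, function(cl) {
    m <- summarizeConfusion(confusionCounts(pred$truth, pred$predicted, cl))
    m[c("precision", "recall", "f1")]
  }, numeric(3L)))
  macro <- colMeans(perClass)
  # scores are oriented toward the second factor level of the labels used in
  # training; flip if the requested positive class is the first
  scores <- pred$score
  if (cm$positive == lev[1L]) scores <- -scores
  ra <- rocAuc(pred$truth, scores, positive = cm$positive)
  foldAcc <- if (!is.null(pred$fold))
    vapply(split(pred, pred$fold),
           function(d) mean(d$truth == d$predicted), 0)
  else numeric(0)
  new("EvalReport", family = family, positiveClass = cm$positive,
      confusion = cm[c("tp", "tn", "fp", "fn")], metrics = metrics,
      perClass = perClass, macro = macro, foldAccuracy = unname(foldAcc),
      roc = ra$roc, auc = ra$auc)
}

#' Plot an ROC curve
#'
#' @param report an [EvalReport-class].
#' @param ... passed to [graphics::plot()].
#' @export
plotROC <- function(report, ...) {
  stopifnot(is(report, "EvalReport"))
  plot(report@roc$fpr, report@roc$tpr, type = "l",
       xlab = "false positive rate", ylab = "true positive rate", ...)
  abline(0, 1, lty = 3, col = "grey")
  legend("bottomright", bty = "n",
         legend = sprintf("%s  AUC = %.3f", report@family, report@auc))
  invisible(NULL)
}

#' Summary table across classifier reports
#'
#' @param reports list of [EvalReport-class] objects.
#' @return data.frame with one row per classifier: accuracy, precision,
#'   recall, F1 (percent) and AUC.
#' @export
evalSummaryTable <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    m <- r@metrics
    data.frame(classifier = r@family, accuracy = m[["accuracy"]],
               precision = m[["precision"]], recall = m[["recall"]],
               f1 = m[["f1"]], auc = r@auc)
  }))
}
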