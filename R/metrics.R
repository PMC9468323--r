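#' Confusion counts for a binary task
#'
#' Tallies true/false positives and negatives with an explicit positive
#' class, so the orientation of sensitivity and specificity is never
#' implicit.
#'
#' @param y_true,y_pred vectors of equal length (coerced to character).
#' @param positive label of the positive (patient) class.
#' @return list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred, positive) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  list(TP = sum(y_true == positive & y_pred == positive),
       FP = sum(y_true != positive & y_pred == positive),
       TN = sum(y_true != positive & y_pred != positive),
       FN = sum(y_true == positive & y_pred != positive))
}

#' Binary classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, precision, and F1 score as
#' exact fractions of the confusion counts.  A metric with a zero
#' denominator is reported as `NA` (undefined) with a warning, never as 0,
#' so that it can be excluded from fold averages.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` (see
#'   [confusion_counts()]).
#' @return named numeric vector: `ACC`, `SEN`, `SPE`, `precision`,
#'   `recall`, `F1`.
#' @export
binary_metrics <- function(counts) {
  with(counts, {
    total <- TP + FP + TN + FN
    stopifnot(total > 0)
    frac <- function(num, den, what) {
      if (den == 0) {
        warning("undefined ", what, " (zero denominator); reported as NA")
        return(NA_real_)
      }
      num / den
    }
    acc <- (TP + TN) / total
    sen <- frac(TP, TP + FN, "sensitivity")
    spe <- frac(TN, TN + FP, "specificity")
    prec <- frac(TP, TP + FP, "precision")
    f1 <- if (is.na(prec) || is.na(sen)) {
      NA_real_
    } else if (prec + sen == 0) {
      warning("undefined F1 (zero denominator); reported as NA")
      NA_real_
    } else 2 * prec * sen / (prec + sen)
    c(ACC = acc, SEN = sen, SPE = spe, precision = prec, recall = sen,
      F1 = f1)
  })
}

#' Multiclass confusion matrix
#'
#' @param y_true,y_pred label vectors.
#' @param classes class order; defaults to factor levels or sorted unique
#'   labels.
#' @return n_classes x n_classes integer matrix, rows = truth,
#'   columns = prediction.
#' @export
multiclass_confusion <- function(y_true, y_pred, classes = NULL) {
  if (is.null(classes))
    classes <- if (is.factor(y_true)) levels(y_true) else
      sort(unique(c(as.character(y_true), as.character(y_pred))))
  y_true <- factor(as.character(y_true), levels = classes)
  y_pred <- factor(as.character(y_pred), levels = classes)
  unclass(table(truth = y_true, prediction = y_pred))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the observed
#' agreement `p_o = trace / total` and the chance term `p_e` from the
#' products of row and column marginals.  When `p_e == 1` the statistic is
#' defined as 1 for perfect agreement and `NA` (with a warning) otherwise.
#'
#' @param confusion square confusion matrix, rows = truth.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), total > 0)
  po <- sum(diag(confusion)) / total
  pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (pe >= 1 - .Machine$double.eps^0.5) {
    if (po >= 1 - .Machine$double.eps^0.5) return(1)
    warning("kappa undefined: chance agreement is 1 with imperfect ",
            "observed agreement")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Jaccard similarity of predicted and true labels
#'
#' Per-class Jaccard index |{i: true_i = c and pred_i = c}| /
#' |{i: true_i = c or pred_i = c}|, macro-averaged over the classes
#' present in the truth (a class absent from both truth and prediction is
#' skipped).  With `average = "positive"` only the designated positive
#' class is reported, the usual convention for binary tasks.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @param average `"macro"` or `"positive"`.
#' @param positive positive-class label, required for
#'   `average = "positive"`.
#' @return Jaccard score in `[0, 1]`.
#' @export
jaccard_score <- function(y_true, y_pred, average = c("macro", "positive"),
                          positive = NULL) {
  average <- match.arg(average)
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  per_class <- function(cl) {
    inter <- sum(y_true == cl & y_pred == cl)
    uni <- sum(y_true == cl | y_pred == cl)
    if (uni == 0) NA_real_ else inter / uni
  }
  if (average == "positive") {
    stopifnot(!is.null(positive))
    return(per_class(positive))
  }
  cls <- sort(unique(y_true))
  vals <- vapply(cls, per_class, 0)
  mean(vals[!is.na(vals)])
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC curve built by sweeping a threshold over
#' the scores of the positive class; tied scores move the curve in a
#' single simultaneous step.
#'
#' @param y_true label vector containing exactly two classes.
#' @param scores numeric scores; larger means more positive.
#' @param positive positive-class label.
#' @return AUC in `[0, 1]`, with attribute `roc` holding the (FPR, TPR)
#'   curve points.
#' @export
roc_auc <- function(y_true, scores, positive) {
  y_true <- as.character(y_true)
  stopifnot(length(y_true) == length(scores))
  is_pos <- y_true == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0)
    stop("undefined AUC: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- is_pos[ord]
  ## group tied scores into single steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(tapply(p, grp, sum))
  fp <- cumsum(tapply(!p, grp, sum))
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  attr(auc, "roc") <- cbind(fpr = fpr, tpr = tpr)
  auc
}

#' Per-class one-vs-rest metrics with macro averages
#'
#' Precision, sensitivity, and F1 for each class treated as positive in
#' turn, plus their macro averages — the standard summary for multiclass
#' tasks alongside overall accuracy, kappa, and Jaccard.
#'
#' @param y_true,y_pred label vectors.
#' @param classes optional class order.
#' @return data.frame with one row per class and an `Avg` row.
#' @export
per_class_metrics <- function(y_true, y_pred, classes = NULL) {
  if (is.null(classes))
    classes <- if (is.factor(y_true)) levels(y_true) else
      sort(unique(as.character(y_true)))
  rows <- lapply(classes, function(cl) {
    m <- suppressWarnings(binary_metrics(confusion_counts(y_true, y_pred, cl)))
    data.frame(class = cl, precision = m["precision"], SEN = m["SEN"],
               F1 = m["F1"], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  avg <- data.frame(class = "Avg",
                    precision = mean(out$precision, na.rm = TRUE),
                    SEN = mean(out$SEN, na.rm = TRUE),
                    F1 = mean(out$F1, na.rm = TRUE))
  rbind(out, avg)
}
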