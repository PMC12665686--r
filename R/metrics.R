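#' Multiclass confusion matrix
#'
#' Entry (a, b) counts cells whose true class is a and predicted class is
#' b: rows are instances of the actual class, columns instances of the
#' predicted class.
#'
#' @param truth,predicted vectors of class labels (character/factor) or
#'   1-based integer indices.
#' @param classes class vocabulary fixing the row/column order; defaults
#'   to the sorted union of the inputs.
#' @return C x C integer matrix with dimnames.
#' @export
confusionMatrix <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  if (!all(truth %in% classes) || !all(predicted %in% classes))
    stop("label outside the class vocabulary", call. = FALSE)
  C <- length(classes)
  cm <- matrix(0L, C, C, dimnames = list(truth = classes, predicted = classes))
  if (length(truth)) {
    tab <- table(factor(truth, classes), factor(predicted, classes))
    cm[] <- as.integer(tab)
  }
  cm
}

#' Accuracy from a confusion matrix
#'
#' Proportion of correctly classified cells: trace / total.
#'
#' @param cm confusion matrix from [confusionMatrix()].
#' @return scalar in [0, 1].
#' @export
accuracyScore <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / tot
}

#' Macro F1 score from a confusion matrix
#'
#' Per class c: precision = TP/column sum, recall = TP/row sum,
#' F1 = 2PR/(P+R); the macro score is the unweighted mean over classes,
#' treating all classes equally regardless of prevalence. A class with
#' P + R = 0 (or undefined P and R) contributes F1 = 0, with a warning.
#'
#' @param cm confusion matrix.
#' @return scalar in [0, 1].
#' @export
macroF1 <- function(cm) {
  if (nrow(cm) < 2L) stop("need at least 2 classes", call. = FALSE)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), NA_real_)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec), 0)
  und <- is.na(prec) & is.na(rec)
  if (any(und))
    warning(sprintf("%d class(es) with no members and no predictions; F1 set to 0",
                    sum(und)))
  mean(f1)
}

#' One-vs-rest AUC per class
#'
#' For each class the AUC of scoring that class against all others,
#' computed exactly as the normalized Mann-Whitney U statistic on the
#' score ranks (ties contribute 1/2) — equivalent to the area under the
#' ROC curve and invariant under strictly monotone score transforms. A
#' class absent from the truth gets NA with a warning.
#'
#' @param truth class labels.
#' @param scores cells x C matrix of per-class scores (probabilities or
#'   arbitrary reals); column names, if present, must cover the classes.
#' @param classes class order; defaults to score column names or the
#'   sorted truth vocabulary.
#' @return named numeric vector of per-class AUCs.
#' @export
ovrAUC <- function(truth, scores, classes = NULL) {
  truth <- as.character(truth)
  if (is.null(classes))
    classes <- if (!is.null(colnames(scores))) colnames(scores)
               else sort(unique(truth))
  if (ncol(scores) != length(classes))
    stop("scores must have one column per class", call. = FALSE)
  auc <- stats::setNames(rep(NA_real_, length(classes)), classes)
  absent <- character()
  for (ci in seq_along(classes)) {
    pos <- truth == classes[ci]
    nPos <- sum(pos); nNeg <- sum(!pos)
    if (nPos == 0L) { absent <- c(absent, classes[ci]); next }
    if (nNeg == 0L) { absent <- c(absent, classes[ci]); next }
    r <- rank(scores[, ci], ties.method = "average")
    auc[ci] <- (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  }
  if (length(absent))
    warning("AUC undefined (class absent from one side): ",
            paste(absent, collapse = ", "))
  auc
}

#' ROC curve points for one class (one-vs-rest)
#'
#' True/false positive rates at every score threshold, for plotting.
#'
#' @param truth class labels.
#' @param score numeric score for the positive class.
#' @param positive the positive class label.
#' @return data.frame with columns `fpr`, `tpr`, `threshold`.
#' @export
rocPoints <- function(truth, score, positive) {
  pos <- as.character(truth) == positive
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  keep <- c(diff(score[ord]) != 0, TRUE)
  data.frame(fpr = c(0, fp[keep] / max(1, sum(!pos))),
             tpr = c(0, tp[keep] / max(1, sum(pos))),
             threshold = c(Inf, score[ord][keep]))
}

#' Full evaluation battery
#'
#' Confusion matrix, accuracy, macro F1 and per-class one-vs-rest AUC in
#' one [MetricsReport-class].
#'
#' @param truth,predicted class label vectors.
#' @param scores optional cells x C score matrix for the AUCs.
#' @param classes class order.
#' @return a [MetricsReport-class].
#' @export
evaluateClassifier <- function(truth, predicted, scores = NULL,
                               classes = NULL) {
  if (is.null(classes))
    classes <- sort(unique(c(as.character(truth), as.character(predicted))))
  cm <- confusionMatrix(truth, predicted, classes)
  auc <- if (!is.null(scores)) suppressWarnings(ovrAUC(truth, scores, classes))
         else stats::setNames(rep(NA_real_, length(classes)), classes)
  methods::new("MetricsReport", confusion = cm,
               accuracy = accuracyScore(cm),
               macroF1 = suppressWarnings(macroF1(cm)),
               perClassAUC = auc, classes = classes)
}

#' Export a metrics report as JSON
#'
#' When `truth` and `scores` are supplied, per-class ROC point arrays are
#' included for plotting.
#'
#' @param report a [MetricsReport-class].
#' @param path output JSON path.
#' @param truth optional true labels (for the ROC arrays).
#' @param scores optional cells x C score matrix (for the ROC arrays).
#' @export
writeMetricsReport <- function(report, path, truth = NULL, scores = NULL) {
  out <- list(
    classes = report@classes,
    confusion = unname(apply(report@confusion, 1L, as.integer, simplify = FALSE)),
    accuracy = report@accuracy,
    macro_f1 = report@macroF1,
    per_class_auc = as.list(report@perClassAUC)
  )
  if (!is.null(truth) && !is.null(scores)) {
    out$roc <- lapply(stats::setNames(seq_along(report@classes),
                                      report@classes), function(ci) {
      r <- rocPoints(truth, scores[, ci], report@classes[ci])
      list(fpr = r$fpr, tpr = r$tpr)
    })
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
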