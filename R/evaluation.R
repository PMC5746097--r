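# Jackknife (leave-one-out) and self-consistency evaluation; per-class
# sensitivity/specificity/MCC from one-vs-rest collapses, overall
# accuracy, and OVR macro-averaged ROC/AUC.

#' Confusion matrix from true and predicted labels
#'
#' @param truth,pred Character vectors of class labels.
#' @param classNames Class ordering (default: order of appearance in
#'   `truth`).
#' @return k x k integer matrix, rows = true class, columns = predicted.
#' @export
confusionCounts <- function(truth, pred, classNames = unique(truth)) {
  stopifnot(length(truth) == length(pred))
  table(factor(truth, levels = classNames),
        factor(pred, levels = classNames))
}

.mcc <- function(tp, fp, tn, fn) {
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (denom == 0) {
    warning("MCC denominator is zero; reporting MCC = 0")
    return(0)
  }
  (tp * tn - fp * fn) / denom
}

#' Per-class Sens/Spec/MCC and overall accuracy
#'
#' Each class is collapsed one-vs-rest: TP the diagonal entry, FN the
#' rest of its row, FP the rest of its column, TN everything else.
#' Sens = TP/(TP+FN), Spec = TN/(TN+FP), MCC from the standard binary
#' formula (0 with a warning when its denominator vanishes). Overall
#' accuracy is trace/n; the macro MCC is the per-class mean.
#'
#' @param cm Confusion matrix ([confusionCounts]).
#' @return List: `perClass` data frame (class, Sens, Spec, MCC), `oa`,
#'   `mccMacro`.
#' @export
perClassMetrics <- function(cm) {
  cm <- as.matrix(cm)
  if (!length(cm) || sum(cm) == 0) stop("empty confusion matrix")
  k <- nrow(cm)
  n <- sum(cm)
  cls <- rownames(cm)
  out <- data.frame(class = cls, Sens = NA_real_, Spec = NA_real_,
                    MCC = NA_real_)
  for (c in seq_len(k)) {
    tp <- cm[c, c]
    fn <- sum(cm[c, ]) - tp
    fp <- sum(cm[, c]) - tp
    tn <- n - tp - fn - fp
    out$Sens[c] <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    out$Spec[c] <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    out$MCC[c] <- .mcc(tp, fp, tn, fn)
  }
  list(perClass = out, oa = sum(diag(cm)) / n,
       mccMacro = mean(out$MCC))
}

#' One-vs-rest macro-averaged ROC and AUC
#'
#' Each class is binarized one-vs-rest and its ROC staircase computed
#' from the per-class score column; the class TPRs are interpolated onto
#' a common FPR grid (101 points on \[0, 1\]) and averaged; the AUC is
#' the trapezoidal area of the averaged curve. A class with constant
#' scores contributes the chance diagonal, with a warning.
#'
#' @param truth Character vector of true labels.
#' @param scores n x k numeric matrix with one column per class (named).
#' @param gridSize Number of FPR grid points (default 101).
#' @return List: `points` data frame (fpr, tpr), `auc`, `perClassAuc`.
#' @export
rocOvr <- function(truth, scores, gridSize = 101) {
  stopifnot(is.matrix(scores), !is.null(colnames(scores)),
            nrow(scores) == length(truth))
  cls <- colnames(scores)
  grid <- seq(0, 1, length.out = gridSize)
  tprs <- matrix(NA_real_, nrow = gridSize, ncol = length(cls))
  aucs <- stats::setNames(numeric(length(cls)), cls)
  for (ci in seq_along(cls)) {
    pos <- truth == cls[ci]
    s <- scores[, ci]
    if (!any(pos) || all(pos) || diff(range(s)) == 0) {
      if (diff(range(s)) == 0)
        warning("constant scores for class ", cls[ci],
                "; using the chance diagonal")
      tprs[, ci] <- grid
      aucs[ci] <- 0.5
      next
    }
    o <- order(s, decreasing = TRUE)
    sp <- s[o]; pp <- pos[o]
    cum_tp <- cumsum(pp); cum_fp <- cumsum(!pp)
    keep <- c(sp[-1] != sp[-length(sp)], TRUE)   # group tied scores
    tpr <- c(0, cum_tp[keep] / sum(pos))
    fpr <- c(0, cum_fp[keep] / sum(!pos))
    aucs[ci] <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
    tprs[, ci] <- stats::approx(fpr, tpr, xout = grid,
                                ties = max, rule = 2)$y
  }
  avg <- rowMeans(tprs)
  auc <- sum(diff(grid) * (avg[-1] + avg[-length(avg)]) / 2)
  list(points = data.frame(fpr = grid, tpr = avg),
       auc = auc, perClassAuc = aucs)
}

.build_report <- function(truth, pred, scores, classNames, protocol) {
  cm <- confusionCounts(truth, pred, classNames)
  met <- perClassMetrics(cm)
  roc <- rocOvr(truth, scores[, classNames, drop = FALSE])
  new("EvalReport", confusion = unclass(cm), perClass = met$perClass,
      oa = met$oa, mccMacro = met$mccMacro, roc = roc$points,
      perClassAuc = roc$perClassAuc, auc = roc$auc, protocol = protocol)
}

#' Jackknife (leave-one-out) evaluation
#'
#' Exactly n folds: fold i trains on the other n - 1 rows and predicts
#' row i. The matrix is used as given (the evaluation-faithful protocol:
#' denoise first, then jackknife); with `leakFree = TRUE` and a
#' `waveletSpec`, denoising is instead refit inside every fold on the
#' training rows only, and the held-out row is denoised 1-D with the
#' training-derived threshold.
#'
#' @param fm A [FeatureMatrix].
#' @param ... Arguments passed to [trainClassifier] (kind, kernel, ...).
#' @param leakFree Refit denoising per fold (default FALSE).
#' @param waveletSpec [WaveletSpec] for `leakFree` mode.
#' @return An [EvalReport] with `protocol = "jackknife"`.
#' @export
jackknife <- function(fm, ..., leakFree = FALSE, waveletSpec = NULL) {
  stopifnot(is(fm, "FeatureMatrix"))
  X <- fm@values
  y <- fm@labels
  n <- nrow(X)
  cls <- unique(y)
  if (n < length(cls) + 1) stop("jackknife needs n >= k + 1")
  pred <- character(n)
  scores <- matrix(NA_real_, n, length(cls),
                   dimnames = list(rownames(X), cls))
  for (i in seq_len(n)) {
    tr_fm <- new("FeatureMatrix",
                 values = X[-i, , drop = FALSE], labels = y[-i],
                 blocks = fm@blocks, params = fm@params)
    te <- X[i, , drop = FALSE]
    if (leakFree && !is.null(waveletSpec)) {
      pyr <- waveletDecompose(tr_fm@values, waveletSpec)
      thr <- if (waveletSpec@thresholdRule == "universal")
        defaultThreshold(pyr) else birgeMassartThresholds(pyr)
      tr_fm@values <- waveletReconstruct(
        applyThreshold(pyr, thr, waveletSpec@thresholdMode))
      rowSpec <- waveletSpec
      dec <- .dwt1_multilevel(as.vector(te),
                              .get_filter(rowSpec@family),
                              rowSpec@extension, rowSpec@level)
      gthr <- if (is.list(thr)) thr else rep(list(
        c(H = thr, V = thr, D = thr)), rowSpec@level)
      for (t in seq_along(dec$details))
        dec$details[[t]] <- .shrink(dec$details[[t]], gthr[[t]][["D"]],
                                    rowSpec@thresholdMode)
      te <- matrix(.idwt1_multilevel(dec, .get_filter(rowSpec@family),
                                     rowSpec@extension), nrow = 1)
    }
    if (length(unique(y[-i])) < length(cls))
      warning("class '", y[i], "' absent from training fold ", i)
    model <- trainClassifier(tr_fm, ...)
    pr <- predict(model, te)
    pred[i] <- pr$labels
    scores[i, colnames(pr$scores)] <- pr$scores[1, ]
  }
  .build_report(y, pred, scores, cls, "jackknife")
}

#' Self-consistency (resubstitution) evaluation
#'
#' Trains on all rows and predicts the same rows.
#'
#' @param fm A [FeatureMatrix].
#' @param ... Arguments passed to [trainClassifier].
#' @return An [EvalReport] with `protocol = "self_consistency"`.
#' @export
selfConsistency <- function(fm, ...) {
  stopifnot(is(fm, "FeatureMatrix"))
  model <- trainClassifier(fm, ...)
  pr <- predict(model, fm@values)
  .build_report(fm@labels, pr$labels, pr$scores, unique(fm@labels),
                "self_consistency")
}
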