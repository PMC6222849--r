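#' Threshold metrics from a confusion matrix
#'
#' Positives are the virion class. Computes
#' \deqn{Sn = TP/(TP+FN),\quad Sp = TN/(TN+FP),\quad
#'       Acc = (TP+TN)/(TP+FN+TN+FP)}
#' and the Matthews correlation coefficient
#' \deqn{Mcc = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' Any zero factor in the Mcc denominator yields Mcc = 0 (the standard
#' degenerate-classifier convention). A metric whose own denominator is zero
#' (e.g. Sn with no positives) is NaN.
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @param scores,labels Optional decision scores and 0/1 labels; when given,
#'   the ROC curve and auROC are attached via [rocCurve()].
#' @return A [MetricsReport].
#' @examples
#' r <- confusionMetrics(tp = 83, fn = 16, fp = 21, tn = 187)
#' c(sn = r@sn, sp = r@sp, acc = r@acc)  # 0.8384, 0.8990, 0.8795
#' @export
confusionMetrics <- function(tp, fn, fp, tn, scores = numeric(0),
                             labels = numeric(0)) {
    counts <- c(tp, fn, fp, tn)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("confusion counts must be non-negative integers")
    if (sum(counts) == 0) stop("empty confusion matrix")
    tp <- as.integer(tp); fn <- as.integer(fn)
    fp <- as.integer(fp); tn <- as.integer(tn)
    sn <- tp / (tp + fn)
    sp <- tn / (tn + fp)
    acc <- (tp + tn) / (tp + fn + fp + tn)
    den <- prod(as.numeric(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    mcc <- if (den == 0) 0 else
        (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
    roc <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("fpr", "tpr")))
    auroc <- NA_real_
    if (length(scores)) {
        rc <- rocCurve(scores, labels)
        roc <- rc$points
        auroc <- rc$auroc
    }
    new("MetricsReport", tp = tp, fn = fn, fp = fp, tn = tn,
        sn = sn, sp = sp, acc = acc, mcc = mcc,
        rocPoints = roc, auroc = auroc,
        scores = as.numeric(scores), labels = as.numeric(labels))
}

#' Pooled metrics from predictions and decision scores
#'
#' Convenience wrapper: builds the confusion matrix from 0/1 predictions
#' against 0/1 truth and attaches the ROC from the continuous scores.
#'
#' @param truth,predicted 0/1 vectors.
#' @param scores Decision scores, higher = more positive.
#' @return A [MetricsReport].
#' @export
metricsFromPredictions <- function(truth, predicted, scores = numeric(0)) {
    truth <- asBinaryLabels(truth)
    predicted <- asBinaryLabels(predicted)
    confusionMetrics(tp = sum(truth == 1 & predicted == 1),
                     fn = sum(truth == 1 & predicted == 0),
                     fp = sum(truth == 0 & predicted == 1),
                     tn = sum(truth == 0 & predicted == 0),
                     scores = scores,
                     labels = if (length(scores)) truth else numeric(0))
}

#' ROC curve and area under it
#'
#' Thresholds descend through the unique score values; all samples sharing a
#' score move across the threshold together (tied blocks), which avoids the
#' optimistic stair-casing of per-sample sweeps. The area is computed by the
#' trapezoidal rule and equals the normalized Mann-Whitney statistic — the
#' probability that a random positive outscores a random negative, ties
#' counted one half.
#'
#' @param scores Real decision values, higher = more positive.
#' @param labels 0/1 class labels, both classes present.
#' @return List with `points` (matrix of fpr, tpr from (0,0) to (1,1)) and
#'   `auroc`.
#' @examples
#' rocCurve(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auroc  # 0.75
#' @export
rocCurve <- function(scores, labels) {
    labels <- asBinaryLabels(labels)
    if (length(scores) != length(labels)) stop("length mismatch")
    nP <- sum(labels == 1); nN <- sum(labels == 0)
    if (nP == 0 || nN == 0) stop("both classes must be present")
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]; l <- labels[o]
    ## block boundaries at changes of the score value
    last <- cumsum(rle(s)$lengths)
    ctp <- cumsum(l)[last]
    cfp <- cumsum(1 - l)[last]
    tpr <- c(0, ctp / nP)
    fpr <- c(0, cfp / nN)
    auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    list(points = cbind(fpr = fpr, tpr = tpr), auroc = auroc)
}

#' @describeIn confusionMetrics Named confusion counts (tp, fn, fp, tn).
#' @export
setMethod("confusionCounts", "MetricsReport", function(x)
    c(tp = x@tp, fn = x@fn, fp = x@fp, tn = x@tn))

#' Export a metrics report as key-value TSV
#'
#' @param x A [MetricsReport].
#' @param path Output path.
#' @param rocPath Optional path for the two-column ROC TSV.
#' @export
writeMetricsTSV <- function(x, path, rocPath = NULL) {
    kv <- data.frame(
        metric = c("TP", "FN", "FP", "TN", "Sn", "Sp", "Acc", "Mcc", "auROC"),
        value = c(x@tp, x@fn, x@fp, x@tn,
                  sprintf("%.2f", 100 * x@sn), sprintf("%.2f", 100 * x@sp),
                  sprintf("%.2f", 100 * x@acc), sprintf("%.4f", x@mcc),
                  sprintf("%.4f", x@auroc)))
    utils::write.table(kv, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rocPath) && nrow(x@rocPoints))
        utils::write.table(x@rocPoints, rocPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    invisible(path)
}
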