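#' SVM and cross-validation configuration
#'
#' Defaults follow common libsvm practice: five stratified folds and
#' log2-spaced grids C in 2^-5..2^15, gamma in 2^-15..2^3. g-gap frequencies
#' already lie in [0, 1], so no rescaling is applied before the SVM.
#'
#' @param C,gamma Point estimates used when no grid search is run.
#' @param nFolds Cross-validation folds (must not exceed the smaller class).
#' @param seed Integer seed controlling fold assignment.
#' @param gridC,gridGamma Candidate values for [gridSearch()].
#' @return A [ModelConfig].
#' @export
modelConfig <- function(C = 1, gamma = 1 / 16, nFolds = 5L, seed = 1L,
                        gridC = 2^seq(-5, 15, by = 2),
                        gridGamma = 2^seq(-15, 3, by = 2)) {
    ## Class= named in full: a slot called "C" would otherwise partially
    ## match new()'s first formal
    new(Class = "ModelConfig", C = C, gamma = gamma,
        nFolds = as.integer(nFolds), seed = as.integer(seed),
        gridC = sort(gridC), gridGamma = sort(gridGamma))
}

#' Stratified cross-validation fold assignment
#'
#' Shuffles each class independently (deterministically under `seed`) and
#' deals samples to folds round-robin, so per-class counts across folds
#' differ by at most one.
#'
#' @param labels 0/1 class labels.
#' @param k Number of folds; must not exceed either class size.
#' @param seed Integer seed.
#' @return Integer fold id (1..k) per sample.
#' @export
stratifiedFolds <- function(labels, k, seed) {
    labels <- asBinaryLabels(labels)
    k <- as.integer(k)
    if (any(table(labels) < k))
        stop("a class has fewer samples than folds (k = ", k, ")")
    fold <- integer(length(labels))
    withSeed(seed, {
        for (cls in c(0, 1)) {
            idx <- which(labels == cls)
            fold[idx[sample.int(length(idx))]] <-
                rep_len(seq_len(k), length(idx))
        }
    })
    fold
}

## Fit one RBF-SVM and return oriented decision scores plus 0/1 predictions
## for the test rows. Orientation: higher score = more likely class 1.
svmFoldPredict <- function(xTrain, yTrain, xTest, C, gamma) {
    fit <- e1071::svm(x = xTrain, y = factor(yTrain, levels = c(0, 1)),
                      kernel = "radial", cost = C, gamma = gamma,
                      scale = FALSE)
    pr <- stats::predict(fit, xTest, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    ## libsvm labels the decision column "<first>/<second>"; positive values
    ## favor the first class named there
    score <- dv[, 1]
    if (sub("/.*", "", colnames(dv)[1]) == "0") score <- -score
    list(predicted = as.numeric(as.character(pr)), score = unname(score))
}

#' Cross-validated RBF-SVM evaluation with pooled metrics
#'
#' Out-of-fold predictions from all folds are pooled into one confusion
#' matrix and one decision-score vector (pooled CV), matching the single
#' Sn/Sp/Acc/Mcc/auROC set reported for the benchmark protocol, rather than
#' averaging per-fold metrics.
#'
#' @param X [GGapFeatureSet] or samples x features matrix.
#' @param y 0/1 labels (from `sampleLabels(X)` when omitted).
#' @param config A [ModelConfig]; its `C`, `gamma`, `nFolds`, `seed` are
#'   used.
#' @param folds Optional precomputed fold assignment (overrides
#'   `config@nFolds`/`config@seed`).
#' @return A [MetricsReport] with ROC/auROC from the pooled scores.
#' @export
cvAccuracy <- function(X, y = NULL, config = modelConfig(), folds = NULL) {
    if (is.null(y) && is(X, "GGapFeatureSet")) y <- sampleLabels(X)
    m <- asSampleMatrix(X)
    y <- asBinaryLabels(y)
    if (is.null(folds))
        folds <- stratifiedFolds(y, config@nFolds, config@seed)
    predicted <- numeric(length(y))
    score <- numeric(length(y))
    for (f in sort(unique(folds))) {
        test <- folds == f
        res <- svmFoldPredict(m[!test, , drop = FALSE], y[!test],
                              m[test, , drop = FALSE],
                              C = config@C, gamma = config@gamma)
        predicted[test] <- res$predicted
        score[test] <- res$score
    }
    metricsFromPredictions(y, predicted, scores = score)
}

#' Exhaustive (C, gamma) grid search by cross-validated accuracy
#'
#' Evaluates every grid point with [cvAccuracy()] on a fixed fold
#' assignment. Ties in accuracy resolve toward the smaller C, then the
#' smaller gamma.
#'
#' @inheritParams cvAccuracy
#' @return List with `C`, `gamma`, `acc`, and `metrics` (the
#'   [MetricsReport] of the winning point).
#' @export
gridSearch <- function(X, y = NULL, config = modelConfig(), folds = NULL) {
    if (is.null(y) && is(X, "GGapFeatureSet")) y <- sampleLabels(X)
    m <- asSampleMatrix(X)
    y <- asBinaryLabels(y)
    if (is.null(folds))
        folds <- stratifiedFolds(y, config@nFolds, config@seed)
    best <- NULL
    for (C in sort(config@gridC)) {
        for (gamma in sort(config@gridGamma)) {
            cfg <- config
            cfg@C <- C; cfg@gamma <- gamma
            rep <- cvAccuracy(m, y, cfg, folds = folds)
            if (is.null(best) || rep@acc > best$acc + 1e-12)
                best <- list(C = C, gamma = gamma, acc = rep@acc,
                             metrics = rep)
        }
    }
    best
}

#' Incremental feature selection sweep over ranked feature prefixes
#'
#' For k = 1, 1 + kStep, ... up to `maxK`, evaluates the prefix of the first
#' k columns of the ranked matrix by cross-validated RBF-SVM accuracy and
#' records the curve. The whole curve is evaluated (no early stopping at the
#' first dip, which would halt on local plateaus); the peak is the smallest
#' k attaining the maximum accuracy.
#'
#' Tuning modes: `"per-k"` re-runs the (C, gamma) grid search at every
#' prefix (honest nested tuning); `"once"` tunes on the full `maxK`-column
#' matrix and reuses that (C, gamma) for every prefix (fast); `"none"` uses
#' `config@C`/`config@gamma` as given.
#'
#' @param Xranked [GGapFeatureSet] or matrix whose columns are already in
#'   ranked order (best feature first).
#' @param y 0/1 labels.
#' @param config A [ModelConfig].
#' @param maxK Largest prefix size (default: all columns).
#' @param kStep Stride between evaluated prefix sizes (maxK always
#'   included).
#' @param tune `"per-k"`, `"once"`, or `"none"`.
#' @return An [IFSCurve].
#' @export
ifsSweep <- function(Xranked, y = NULL, config = modelConfig(),
                     maxK = NULL, kStep = 1L,
                     tune = c("per-k", "once", "none")) {
    tune <- match.arg(tune)
    if (is.null(y) && is(Xranked, "GGapFeatureSet")) y <- sampleLabels(Xranked)
    m <- asSampleMatrix(Xranked)
    y <- asBinaryLabels(y)
    if (is.null(maxK)) maxK <- ncol(m)
    if (maxK > ncol(m)) stop("maxK exceeds feature count")
    sizes <- unique(c(seq(1L, maxK, by = as.integer(kStep)), maxK))
    folds <- stratifiedFolds(y, config@nFolds, config@seed)

    if (tune == "once") {
        g <- gridSearch(m[, seq_len(maxK), drop = FALSE], y, config, folds)
        config@C <- g$C; config@gamma <- g$gamma
    }
    acc <- numeric(length(sizes))
    cc <- numeric(length(sizes)); gg <- numeric(length(sizes))
    reports <- vector("list", length(sizes))
    for (i in seq_along(sizes)) {
        sub <- m[, seq_len(sizes[i]), drop = FALSE]
        if (tune == "per-k") {
            g <- gridSearch(sub, y, config, folds)
            acc[i] <- g$acc; reports[[i]] <- g$metrics
            cc[i] <- g$C; gg[i] <- g$gamma
        } else {
            rep <- cvAccuracy(sub, y, config, folds)
            acc[i] <- rep@acc; reports[[i]] <- rep
            cc[i] <- config@C; gg[i] <- config@gamma
        }
    }
    peak <- which.max(acc)   # first maximum = smallest k
    new("IFSCurve", sizes = as.integer(sizes), accuracies = acc,
        peakK = as.integer(sizes[peak]), peakMetrics = reports[[peak]],
        params = S4Vectors::DataFrame(k = as.integer(sizes), C = cc,
                                      gamma = gg))
}

#' @describeIn ifsSweep Smallest prefix size attaining the accuracy maximum.
#' @export
setMethod("peakK", "IFSCurve", function(x) x@peakK)

#' @describeIn ifsSweep Accuracy at each evaluated prefix size.
#' @export
setMethod("accuracies", "IFSCurve", function(x)
    stats::setNames(x@accuracies, x@sizes))

#' @describeIn ifsSweep Full [MetricsReport] at the peak.
#' @export
setMethod("peakMetrics", "IFSCurve", function(x) x@peakMetrics)

#' Export an IFS curve as two-column TSV (k, Acc)
#'
#' @param x An [IFSCurve].
#' @param path Output path.
#' @export
writeCurveTSV <- function(x, path) {
    utils::write.table(data.frame(k = x@sizes, Acc = x@accuracies), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
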