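#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importClassesFrom S4Vectors DataFrame
NULL

#' The 20 standard amino acids, alphabetical
#'
#' Character vector of the one-letter codes accepted throughout the package.
#' Residues outside this alphabet (including ambiguity codes B, U, X, Z and
#' the stop character `*`) are rejected at read time.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' GGapFeatureSet: g-gap dipeptide feature matrix
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' features x samples matrix of g-gap dipeptide frequencies (assay
#' \code{"freq"}). \code{rowData} carries the per-feature descriptors
#' (\code{g}, \code{first}, \code{second}, \code{dipIndex}); \code{colData}
#' carries sample ids and the binary class label (1 = virion, 0 =
#' non-virion, NA = unlabeled).
#'
#' All entries lie in [0, 1]; a single-g matrix has unit column sums because
#' each sequence of length L contributes exactly L - g - 1 ordered pairs.
#'
#' @seealso [ggapMatrix()], [fuseMatrices()], [featureValues()]
#' @export
setClass("GGapFeatureSet", contains = "SummarizedExperiment")

setValidity("GGapFeatureSet", function(object) {
    msg <- NULL
    if (!"freq" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'freq' is required")
    else {
        v <- SummarizedExperiment::assay(object, "freq")
        if (any(v < -1e-12 | v > 1 + 1e-12))
            msg <- c(msg, "frequencies must lie in [0, 1]")
    }
    rd <- SummarizedExperiment::rowData(object)
    need <- c("g", "first", "second", "dipIndex")
    if (!all(need %in% colnames(rd)))
        msg <- c(msg, paste("rowData must contain", paste(need, collapse = ", ")))
    if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain 'label'")
    if (is.null(msg)) TRUE else msg
})

#' AnovaResult: per-feature one-way ANOVA decomposition
#'
#' Holds the F statistic and its sum-of-squares decomposition for every
#' feature: F(i) = (SS_B(i)/df_B) / (SS_W(i)/df_W) with df_B = K - 1 and
#' df_W = M - K for K groups and M samples.
#'
#' @slot fScores numeric, per-feature F value (Inf for a perfectly
#'   separating feature with zero within-group variance; 0 for a constant
#'   feature).
#' @slot ssBetween,ssWithin numeric, per-feature sums of squares.
#' @slot dfBetween,dfWithin integer degrees of freedom.
#' @slot nGroups,nSamples integer K and M.
#' @slot groupSizes integer vector m_j.
#' @export
setClass("AnovaResult", representation(
    fScores = "numeric", ssBetween = "numeric", ssWithin = "numeric",
    dfBetween = "integer", dfWithin = "integer",
    nGroups = "integer", nSamples = "integer", groupSizes = "integer"))

setValidity("AnovaResult", function(object) {
    msg <- NULL
    if (object@dfBetween != object@nGroups - 1L)
        msg <- c(msg, "dfBetween must equal nGroups - 1")
    if (object@dfWithin != object@nSamples - object@nGroups)
        msg <- c(msg, "dfWithin must equal nSamples - nGroups")
    if (sum(object@groupSizes) != object@nSamples)
        msg <- c(msg, "group sizes must sum to nSamples")
    if (any(object@fScores < 0, na.rm = TRUE))
        msg <- c(msg, "F scores must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' RankedFeatures: a descending-score feature ordering
#'
#' @slot order integer permutation of feature indices (1-based), best first.
#' @slot scores numeric scores aligned with \code{order} (non-increasing).
#' @slot descriptors DataFrame of per-feature provenance aligned with
#'   \code{order} (typically g / first / second / name).
#' @export
setClass("RankedFeatures", representation(
    order = "integer", scores = "numeric", descriptors = "DataFrame"))

setValidity("RankedFeatures", function(object) {
    msg <- NULL
    n <- length(object@order)
    if (length(object@scores) != n)
        msg <- c(msg, "scores and order lengths differ")
    if (anyDuplicated(object@order))
        msg <- c(msg, "order must not repeat indices")
    fin <- is.finite(object@scores)
    if (n > 1 && any(diff(object@scores[fin]) > 1e-9))
        msg <- c(msg, "scores must be non-increasing along order")
    if (nrow(object@descriptors) != n)
        msg <- c(msg, "descriptors must align with order")
    if (is.null(msg)) TRUE else msg
})

#' DiscreteMatrix: binned feature codes for mutual-information estimation
#'
#' @slot codes integer matrix, samples x features, values in 0..(nBins-1).
#' @slot nBins integer number of bins.
#' @slot boundaries list of per-feature strictly increasing cut points.
#' @export
setClass("DiscreteMatrix", representation(
    codes = "matrix", nBins = "integer", boundaries = "list"))

setValidity("DiscreteMatrix", function(object) {
    msg <- NULL
    if (any(object@codes < 0L | object@codes >= object@nBins))
        msg <- c(msg, "codes must lie in [0, nBins)")
    if (length(object@boundaries) != ncol(object@codes))
        msg <- c(msg, "one boundary vector per feature required")
    if (is.null(msg)) TRUE else msg
})

#' ModelConfig: SVM and cross-validation settings
#'
#' @slot C positive soft-margin penalty.
#' @slot gamma positive RBF kernel width.
#' @slot nFolds folds for cross-validation (default 5).
#' @slot seed integer seed controlling fold assignment.
#' @slot gridC,gridGamma candidate values searched by [gridSearch()].
#' @export
setClass("ModelConfig", representation(
    C = "numeric", gamma = "numeric", nFolds = "integer", seed = "integer",
    gridC = "numeric", gridGamma = "numeric"))

setValidity("ModelConfig", function(object) {
    msg <- NULL
    if (object@C <= 0) msg <- c(msg, "C must be positive")
    if (object@gamma <= 0) msg <- c(msg, "gamma must be positive")
    if (object@nFolds < 2L) msg <- c(msg, "nFolds must be at least 2")
    if (any(object@gridC <= 0) || any(object@gridGamma <= 0))
        msg <- c(msg, "grid values must be positive")
    if (is.null(msg)) TRUE else msg
})

#' MetricsReport: confusion counts, threshold metrics and ROC
#'
#' @slot tp,fn,fp,tn integer confusion counts (positives = virion class).
#' @slot sn,sp,acc proportions in [0, 1].
#' @slot mcc Matthews correlation coefficient in [-1, 1]; 0 when any
#'   denominator factor vanishes.
#' @slot rocPoints two-column matrix (fpr, tpr), empty when no scores kept.
#' @slot auroc area under the ROC curve (NA when no scores kept).
#' @slot scores,labels numeric decision scores and 0/1 labels backing the ROC.
#' @export
setClass("MetricsReport", representation(
    tp = "integer", fn = "integer", fp = "integer", tn = "integer",
    sn = "numeric", sp = "numeric", acc = "numeric", mcc = "numeric",
    rocPoints = "matrix", auroc = "numeric",
    scores = "numeric", labels = "numeric"))

#' IFSCurve: incremental feature selection accuracy profile
#'
#' @slot sizes strictly increasing prefix sizes k evaluated.
#' @slot accuracies cross-validated pooled accuracy at each k.
#' @slot peakK smallest k attaining the maximum accuracy.
#' @slot peakMetrics [MetricsReport] at the peak.
#' @slot params DataFrame of the (C, gamma) used at each k.
#' @export
setClass("IFSCurve", representation(
    sizes = "integer", accuracies = "numeric", peakK = "integer",
    peakMetrics = "MetricsReport", params = "DataFrame"))

setValidity("IFSCurve", function(object) {
    msg <- NULL
    if (length(object@sizes) != length(object@accuracies))
        msg <- c(msg, "sizes and accuracies lengths differ")
    if (is.unsorted(object@sizes, strictly = TRUE))
        msg <- c(msg, "sizes must be strictly increasing")
    if (any(object@accuracies < 0 | object@accuracies > 1))
        msg <- c(msg, "accuracies must lie in [0, 1]")
    if (!(object@peakK %in% object@sizes))
        msg <- c(msg, "peakK must be one of the evaluated sizes")
    if (is.null(msg)) TRUE else msg
})

#' SynthSpec: synthetic labeled-FASTA generator settings
#'
#' Describes a two-class synthetic benchmark: negatives drawn i.i.d. from a
#' background residue distribution, positives drawn from the same background
#' but with selected g-gap dipeptide pairs enriched by biased sequential
#' sampling.
#'
#' @slot nPos,nNeg class sizes.
#' @slot lengthRange integer min/max sequence length.
#' @slot background length-20 residue probability vector (alphabetical).
#' @slot planted DataFrame with columns g, first, second, enrichment.
#' @slot seed integer seed; generation is deterministic given the spec.
#' @export
setClass("SynthSpec", representation(
    nPos = "integer", nNeg = "integer", lengthRange = "integer",
    background = "numeric", planted = "DataFrame", seed = "integer"))

setValidity("SynthSpec", function(object) {
    msg <- NULL
    if (length(object@background) != 20L ||
        abs(sum(object@background) - 1) > 1e-9 ||
        any(object@background <= 0))
        msg <- c(msg, "background must be 20 positive frequencies summing to 1")
    if (length(object@lengthRange) != 2L ||
        object@lengthRange[1] > object@lengthRange[2])
        msg <- c(msg, "lengthRange must be (min, max) with min <= max")
    p <- object@planted
    if (nrow(p) > 0) {
        if (!all(c("g", "first", "second", "enrichment") %in% colnames(p)))
            msg <- c(msg, "planted needs columns g, first, second, enrichment")
        else {
            if (any(p$enrichment <= 0))
                msg <- c(msg, "enrichment factors must be positive")
            if (object@lengthRange[1] < max(p$g) + 2L)
                msg <- c(msg, "minimum length must be >= max planted g + 2")
        }
    }
    if (is.null(msg)) TRUE else msg
})
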