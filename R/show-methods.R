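#' @describeIn accessors Compact display of a feature set.
#' @param object Object to display.
#' @export
setMethod("show", "GGapFeatureSet", function(object) {
    g <- unique(SummarizedExperiment::rowData(object)$g)
    lab <- SummarizedExperiment::colData(object)$label
    cat("GGapFeatureSet:", nrow(object), "features x", ncol(object),
        "samples\n")
    cat("  gap values:", paste(sort(g), collapse = ", "), "\n")
    cat("  labels: ", sum(lab == 1, na.rm = TRUE), " positive / ",
        sum(lab == 0, na.rm = TRUE), " negative\n", sep = "")
})

#' @describeIn accessors Display an ANOVA decomposition summary.
#' @export
setMethod("show", "AnovaResult", function(object) {
    cat("AnovaResult:", length(object@fScores), "features,",
        object@nGroups, "groups,", object@nSamples, "samples\n")
    cat("  df_B =", object@dfBetween, ", df_W =", object@dfWithin, "\n")
    fin <- is.finite(object@fScores)
    cat("  F range:", signif(min(object@fScores[fin]), 4), "..",
        signif(max(object@fScores[fin]), 4),
        if (any(!fin)) paste0(" (+", sum(!fin), " infinite)") else "", "\n")
})

#' @describeIn accessors Display the top of a feature ranking.
#' @export
setMethod("show", "RankedFeatures", function(object) {
    n <- length(object@order)
    cat("RankedFeatures:", n, "features\n")
    top <- utils::head(seq_len(n), 5)
    nm <- if ("name" %in% colnames(object@descriptors))
        object@descriptors$name[top]
    else paste0("g", object@descriptors$g[top], "_",
                object@descriptors$first[top], object@descriptors$second[top])
    cat("  top:", paste(sprintf("%s (%.4g)", nm, object@scores[top]),
                        collapse = ", "), "\n")
})

#' @describeIn accessors Display an IFS curve summary.
#' @export
setMethod("show", "IFSCurve", function(object) {
    cat("IFSCurve:", length(object@sizes), "prefix sizes, k =",
        min(object@sizes), "..", max(object@sizes), "\n")
    cat(sprintf("  peak: Acc %.4f at k = %d\n", max(object@accuracies),
                object@peakK))
})

#' @describeIn accessors Display a metrics report.
#' @export
setMethod("show", "MetricsReport", function(object) {
    cat("MetricsReport  (TP", object@tp, "FN", object@fn, "FP", object@fp,
        "TN", object@tn, ")\n")
    cat(sprintf("  Sn %.2f%%  Sp %.2f%%  Acc %.2f%%  Mcc %.4f",
                100 * object@sn, 100 * object@sp, 100 * object@acc,
                object@mcc))
    if (!is.na(object@auroc)) cat(sprintf("  auROC %.4f", object@auroc))
    cat("\n")
})

#' @describeIn accessors Display a synthetic benchmark spec.
#' @export
setMethod("show", "SynthSpec", function(object) {
    cat("SynthSpec:", object@nPos, "positive /", object@nNeg,
        "negative, lengths", object@lengthRange[1], "-",
        object@lengthRange[2], ", seed", object@seed, "\n")
    p <- object@planted
    if (nrow(p))
        cat("  planted:", paste(sprintf("g%d:%s%s x%g", p$g, p$first,
                                        p$second, p$enrichment),
                                collapse = ", "), "\n")
    else cat("  planted: none (null model)\n")
})
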