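#' One-way ANOVA F scores for every feature
#'
#' For each feature (column of the samples x features matrix) the between-
#' and within-group sums of squares about the grand mean are formed and the
#' F statistic computed as
#' \deqn{F = \frac{SS_B / (K-1)}{SS_W / (M-K)}}
#' for K groups and M samples. A high F marks a feature whose class means
#' are well separated relative to its within-class spread, which is the
#' univariate relevance filter driving the first selection stage. The
#' pipeline uses K = 2 (virion vs non-virion) but the decomposition is
#' implemented for any K >= 2.
#'
#' Degenerate features: zero within-group variance with non-zero
#' between-group variance gives F = Inf (a perfectly separating feature must
#' outrank every finite score); an entirely constant feature (0/0) gives
#' F = 0 (no discriminative signal).
#'
#' @param X [GGapFeatureSet] or samples x features matrix.
#' @param y Group labels (any vector with >= 2 distinct values; taken from
#'   `sampleLabels(X)` when omitted and X is a `GGapFeatureSet`).
#' @return An [AnovaResult].
#' @examples
#' X <- cbind(f = c(1, 2, 3, 4, 5, 6))
#' anovaFScores(X, c(0, 0, 0, 1, 1, 1))  # F = 13.5
#' @export
anovaFScores <- function(X, y = NULL) {
    if (is.null(y) && is(X, "GGapFeatureSet")) y <- sampleLabels(X)
    m <- asSampleMatrix(X)
    grp <- factor(y)
    K <- nlevels(grp)
    M <- nrow(m)
    if (length(y) != M) stop("label length does not match sample count")
    if (K < 2L) stop("at least two groups are required")
    if (M <= K) stop("need more samples than groups (df_W = M - K >= 1)")
    sizes <- as.integer(table(grp))

    ## group sums per feature via indicator crossprod: K x p
    ind <- stats::model.matrix(~ grp - 1)
    gSums <- crossprod(ind, m)                 # K x p
    gMeans <- gSums / sizes
    grand <- colMeans(m)
    ssb <- colSums(sizes * (gMeans - rep(grand, each = K))^2)
    sst <- colSums((m - rep(grand, each = M))^2)
    ssw <- pmax(sst - ssb, 0)

    dfB <- K - 1L
    dfW <- M - K
    f <- rep(0, ncol(m))
    tol <- 1e-12 * pmax(sst, 1e-300)
    zeroW <- ssw <= tol
    zeroB <- ssb <= tol
    ok <- !zeroW
    f[ok] <- (ssb[ok] / dfB) / (ssw[ok] / dfW)
    f[zeroW & !zeroB] <- Inf
    f[zeroW & zeroB] <- 0
    names(f) <- colnames(m)

    new("AnovaResult", fScores = f, ssBetween = unname(ssb),
        ssWithin = unname(ssw), dfBetween = dfB, dfWithin = dfW,
        nGroups = K, nSamples = M, groupSizes = sizes)
}

#' Rank features by score, high to low
#'
#' Stable descending sort: ties are broken by ascending original feature
#' index, and Inf sentinels sort above every finite score.
#'
#' @param scores Per-feature numeric scores.
#' @param descriptors Optional DataFrame/data.frame of per-feature
#'   annotation (one row per score, reordered alongside).
#' @return A [RankedFeatures].
#' @export
rankByScore <- function(scores, descriptors = NULL) {
    nm <- names(scores)
    scores <- as.numeric(scores)
    n <- length(scores)
    if (is.null(descriptors))
        descriptors <- S4Vectors::DataFrame(
            name = if (is.null(nm)) paste0("f", seq_len(n)) else nm)
    descriptors <- as(descriptors, "DataFrame")
    if (nrow(descriptors) != n) stop("descriptors must align with scores")
    o <- order(scores, decreasing = TRUE, method = "radix")
    new("RankedFeatures", order = as.integer(o), scores = scores[o],
        descriptors = descriptors[o, , drop = FALSE])
}

#' @describeIn anovaFScores Per-feature F values.
#' @export
setMethod("fScores", "AnovaResult", function(x) x@fScores)

#' @describeIn rankByScore Ranked feature indices, best first.
#' @export
setMethod("rankOrder", "RankedFeatures", function(x) x@order)

#' @describeIn rankByScore Scores aligned with the ranking.
#' @export
setMethod("rankScores", "RankedFeatures", function(x) x@scores)

#' Export a ranking as TSV (rank, feature, score)
#'
#' @param x A [RankedFeatures].
#' @param path Output path.
#' @param extra Optional named list of extra aligned columns (e.g. Z-scores).
#' @export
writeRankingTSV <- function(x, path, extra = NULL) {
    nm <- if ("name" %in% colnames(x@descriptors)) x@descriptors$name
          else paste0("g", x@descriptors$g, "_", x@descriptors$first,
                      x@descriptors$second)
    df <- data.frame(rank = seq_along(x@order), feature = nm,
                     index = x@order, score = x@scores)
    for (col in names(extra)) df[[col]] <- extra[[col]]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
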