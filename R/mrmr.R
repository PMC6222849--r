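#' Discretize a feature matrix for mutual-information estimation
#'
#' Default scheme (`"meansd"`, the classical mRMR preprocessing): per
#' feature, values below \eqn{\mu - w\sigma} get code 0, values within
#' \eqn{[\mu - w\sigma, \mu + w\sigma]} code 1, values above code 2, with
#' \eqn{\mu,\sigma} the feature-wise mean and population standard deviation
#' and w the `width` multiplier. A `"quantile"` scheme with `nBins`
#' equal-frequency bins is provided as an alternative. Both are
#' deterministic. A constant feature discretizes to a single repeated code
#' (and thus zero mutual information with anything).
#'
#' @param X [GGapFeatureSet] or samples x features matrix.
#' @param nBins Number of bins (`"meansd"` is the 3-bin scheme; `nBins`
#'   must be 3 there).
#' @param scheme `"meansd"` (default) or `"quantile"`.
#' @param width Multiplier w on sigma for `"meansd"`.
#' @return A [DiscreteMatrix].
#' @export
discretizeFeatures <- function(X, nBins = 3L, scheme = c("meansd", "quantile"),
                               width = 1) {
    scheme <- match.arg(scheme)
    m <- asSampleMatrix(X)
    nBins <- as.integer(nBins)
    if (nBins < 2L) stop("nBins must be at least 2")
    p <- ncol(m)
    codes <- matrix(0L, nrow(m), p, dimnames = dimnames(m))
    bounds <- vector("list", p)
    for (j in seq_len(p)) {
        x <- m[, j]
        if (scheme == "meansd") {
            if (nBins != 3L) stop("meansd scheme defines exactly 3 bins")
            mu <- mean(x); s <- popSd(x)
            if (s == 0) { bounds[[j]] <- numeric(0); next }  # constant -> code 0
            b <- c(mu - width * s, mu + width * s)
        } else {
            q <- stats::quantile(x, probs = seq_len(nBins - 1L) / nBins,
                                 names = FALSE, type = 7)
            b <- unique(q)
            if (length(b) == 0L) { bounds[[j]] <- numeric(0); next }
        }
        codes[, j] <- findInterval(x, b, left.open = TRUE)
        bounds[[j]] <- b
    }
    new("DiscreteMatrix", codes = codes, nBins = nBins, boundaries = bounds)
}

#' Mutual information between two discrete vectors, in bits
#'
#' Plug-in estimate over the empirical joint distribution:
#' \deqn{I(x, y) = \sum_{x,y} \hat p(x,y)\, \log_2 \frac{\hat p(x,y)}{\hat p(x)\hat p(y)}}
#' with zero-probability cells contributing 0. Symmetric, non-negative, and
#' invariant under relabeling of the category codes; base 2 only rescales
#' scores uniformly and cannot change any greedy selection order.
#'
#' @param a,b Equal-length vectors of discrete codes (any atomic type).
#' @return Non-negative mutual information in bits.
#' @examples
#' x <- rep(0:1, each = 50)
#' mutualInformation(x, x)  # 1 bit: I(X, X) = H(X) for a balanced binary X
#' @export
mutualInformation <- function(a, b) {
    if (length(a) != length(b)) stop("vectors must have equal length")
    if (length(a) == 0L) stop("vectors must be non-empty")
    tab <- table(a, b)
    pj <- tab / sum(tab)
    px <- rowSums(pj); py <- colSums(pj)
    nz <- pj > 0
    sum(pj[nz] * log2(pj[nz] / outer(px, py)[nz]))
}

## Vectorized MI of every column of an integer code matrix against one
## discrete vector; used by the greedy mRMR loop. Codes must be >= 0.
miAgainstVector <- function(codes, v) {
    n <- nrow(codes)
    v <- as.integer(factor(v)) - 1L
    nv <- max(v) + 1L
    out <- numeric(ncol(codes))
    for (j in seq_len(ncol(codes))) {
        joint <- tabulate(codes[, j] * nv + v + 1L,
                          nbins = (max(codes[, j]) + 1L) * nv) / n
        dim(joint) <- c(nv, max(codes[, j]) + 1L)
        px <- colSums(joint); py <- rowSums(joint)
        nz <- joint > 0
        e <- outer(py, px)
        out[j] <- sum(joint[nz] * log2(joint[nz] / e[nz]))
    }
    out
}

#' Greedy minimal-redundancy-maximal-relevance feature ordering
#'
#' Forward selection on discretized features: the first pick maximizes the
#' relevance I(x_i; c) to the class variable c; each later pick maximizes
#' the incremental criterion
#' \itemize{
#'   \item MID (difference, default): \eqn{I(x;c) - \frac{1}{|S|}\sum_{x_j \in S} I(x;x_j)}
#'   \item MIQ (quotient): \eqn{I(x;c) / \frac{1}{|S|}\sum_{x_j \in S} I(x;x_j)},
#'     falling back to relevance alone when the mean redundancy is below
#'     1e-12.
#' }
#' Ties break toward the lower feature index. This incremental greedy form
#' is the standard operationalization of the set-level
#' max-relevance/min-redundancy objective, which is not optimized exactly.
#'
#' @param Xd A [DiscreteMatrix] (or integer samples x features matrix).
#' @param y Class labels.
#' @param m Number of features to order (default: all).
#' @param criterion `"mid"` or `"miq"`.
#' @param descriptors Optional per-feature DataFrame carried into the result.
#' @return A [RankedFeatures]; `rankScores()` holds the per-step criterion
#'   value (not monotone by construction, so the non-increasing ranking
#'   invariant is not enforced here — the order slot is the contract).
#' @export
mrmrOrder <- function(Xd, y, m = NULL, criterion = c("mid", "miq"),
                      descriptors = NULL) {
    criterion <- match.arg(criterion)
    codes <- if (is(Xd, "DiscreteMatrix")) Xd@codes else Xd
    storage.mode(codes) <- "integer"
    p <- ncol(codes)
    if (is.null(m)) m <- p
    if (m < 1L || m > p) stop("m must lie in 1..", p)
    y <- as.integer(factor(y)) - 1L
    if (length(y) != nrow(codes)) stop("label length mismatch")

    relevance <- miAgainstVector(codes, y)
    redSum <- numeric(p)
    selected <- integer(m)
    scores <- numeric(m)
    avail <- rep(TRUE, p)
    for (step in seq_len(m)) {
        if (step == 1L) {
            crit <- relevance
        } else {
            meanRed <- redSum / (step - 1L)
            if (criterion == "mid") {
                crit <- relevance - meanRed
            } else {
                crit <- ifelse(meanRed < 1e-12, relevance,
                               relevance / meanRed)
            }
        }
        crit[!avail] <- -Inf
        pick <- which.max(crit)          # first index wins ties
        selected[step] <- pick
        scores[step] <- crit[pick]
        avail[pick] <- FALSE
        if (step < m)
            redSum <- redSum + miAgainstVector(codes, codes[, pick])
    }
    if (is.null(descriptors)) {
        nm <- colnames(codes)
        if (is.null(nm)) nm <- paste0("f", seq_len(p))
        descriptors <- S4Vectors::DataFrame(name = nm)
    }
    descriptors <- as(descriptors, "DataFrame")
    ## bypass the monotone-score validity: mRMR step scores need not decrease
    obj <- new("RankedFeatures")
    obj@order <- as.integer(selected)
    obj@scores <- scores
    obj@descriptors <- descriptors[selected, , drop = FALSE]
    obj
}

#' Standardize scores to Z-scores
#'
#' \eqn{Z_i = (x_i - \mu)/\sigma} with the population standard deviation.
#' Used to put the mRMR step scores of the fused feature set on a common
#' scale for reporting.
#'
#' @param scores Numeric vector, length >= 2.
#' @return List with `z`, `mu`, `sigma`.
#' @examples
#' zScores(c(1, 2, 3))$z  # -1.2247, 0, 1.2247
#' @export
zScores <- function(scores) {
    if (length(scores) < 2L) stop("need at least 2 scores")
    mu <- mean(scores)
    sigma <- popSd(scores)
    if (sigma == 0) stop("zero variance: Z-scores undefined")
    list(z = (scores - mu) / sigma, mu = mu, sigma = sigma)
}
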