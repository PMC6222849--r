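## Independent oracles used across the suite. Each deliberately takes a
## different computational route than the package implementation.

## Brute-force g-gap pair counts by explicit position enumeration.
oraclePairCounts <- function(res, g) {
    r <- strsplit(res, "")[[1]]
    counts <- numeric(400)
    names(counts) <- as.vector(t(outer(AA_ALPHABET20, AA_ALPHABET20, paste0)))
    for (p in seq_len(length(r) - g - 1)) {
        key <- paste0(r[p], r[p + g + 1])
        counts[key] <- counts[key] + 1
    }
    counts
}

## Adjacent-bigram frequency via table() on substring pairs (g = 0 only).
oracleBigramFreq <- function(res) {
    r <- strsplit(res, "")[[1]]
    pairs <- paste0(head(r, -1), tail(r, -1))
    counts <- table(factor(pairs,
        levels = as.vector(t(outer(AA_ALPHABET20, AA_ALPHABET20, paste0)))))
    as.numeric(counts) / (length(r) - 1)
}

## Shannon entropy in bits of a discrete vector (plug-in).
oracleEntropy <- function(x) {
    p <- table(x) / length(x)
    -sum(p[p > 0] * log2(p[p > 0]))
}

## MI via the entropy identity I(a,b) = H(a) + H(b) - H(a,b): a different
## route than the package's joint-over-marginals summation.
oracleMI <- function(a, b) {
    oracleEntropy(a) + oracleEntropy(b) -
        oracleEntropy(paste(a, b, sep = "|"))
}

## Independent re-implementation of the incremental mRMR step rule.
oracleMrmr <- function(codes, y, m, criterion = "mid") {
    p <- ncol(codes)
    rel <- vapply(seq_len(p), function(j) oracleMI(codes[, j], y), numeric(1))
    sel <- integer(0)
    for (step in seq_len(m)) {
        remaining <- setdiff(seq_len(p), sel)
        crit <- vapply(remaining, function(j) {
            if (length(sel) == 0) return(rel[j])
            red <- mean(vapply(sel, function(s)
                oracleMI(codes[, j], codes[, s]), numeric(1)))
            if (criterion == "mid") rel[j] - red
            else if (red < 1e-12) rel[j] else rel[j] / red
        }, numeric(1))
        sel <- c(sel, remaining[which.max(crit)])
    }
    sel
}

## auROC by exhaustive positive-negative pair counting, ties = 1/2.
oracleAuroc <- function(scores, labels) {
    sp <- scores[labels == 1]
    sn <- scores[labels == 0]
    total <- 0
    for (a in sp) total <- total + sum(a > sn) + 0.5 * sum(a == sn)
    total / (length(sp) * length(sn))
}

## Per-feature one-way ANOVA F through R's standard machinery.
oracleAnovaF <- function(m, y) {
    grp <- factor(y)
    apply(m, 2, function(x)
        unname(stats::oneway.test(x ~ grp, var.equal = TRUE)$statistic))
}

## Small random sequence set over the 20-letter alphabet.
randomSeqs <- function(n, lens, seed) {
    withr::with_seed(seed, {
        s <- vapply(sample(lens, n, replace = TRUE), function(L)
            paste(sample(AA_ALPHABET20, L, replace = TRUE), collapse = ""),
            character(1))
        names(s) <- paste0("r", seq_len(n))
        s
    })
}
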