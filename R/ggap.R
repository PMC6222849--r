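#' Index of an ordered dipeptide within the 400-dimensional descriptor block
#'
#' The 400 ordered amino-acid pairs are laid out row-major by alphabetical
#' rank of the first residue, then the second: (A,A) = 0, (A,C) = 1, ...,
#' (Y,Y) = 399. The ordering is a free choice — any bijection gives the same
#' model — but fixing it makes ranked-feature output reproducible.
#'
#' @param first,second One-letter amino-acid codes (vectorized).
#' @return Integer index in 0..399.
#' @examples
#' dipeptideIndex("A", "A")  # 0
#' dipeptideIndex("Y", "Y")  # 399
#' @export
dipeptideIndex <- function(first, second) {
    r1 <- match(first, AA_ALPHABET20)
    r2 <- match(second, AA_ALPHABET20)
    if (anyNA(r1) || anyNA(r2))
        stop("residue outside the 20-letter alphabet: ",
             paste(unique(c(first[is.na(r1)], second[is.na(r2)])), collapse = ", "))
    20L * (r1 - 1L) + (r2 - 1L)
}

## Names for the 400 descriptors of one g-block, e.g. "g1_AC".
ggapFeatureNames <- function(g) {
    pairs <- expand.grid(second = AA_ALPHABET20, first = AA_ALPHABET20,
                         stringsAsFactors = FALSE)[, c("first", "second")]
    paste0("g", g, "_", pairs$first, pairs$second)
}

#' g-gap dipeptide composition of one sequence
#'
#' Counts ordered residue pairs (position p, position p + g + 1) for
#' p = 1 .. L - g - 1 and divides by L - g - 1, giving a 400-vector of
#' frequencies that sums to exactly 1. g = 0 recovers the classical adjacent
#' dipeptide composition; g = 1 pairs residues separated by one intervening
#' position, and so on.
#'
#' @param seq Residue string, `AAString`, or single-element `AAStringSet`.
#' @param g Gap size, a non-negative integer (0..9 in the standard pipeline).
#' @return Named numeric vector of length 400 (names as in
#'   [ggapFeatureNames]'s `g{g}_{XY}` scheme).
#' @examples
#' v <- ggapVector("ACDE", g = 0)
#' v[v > 0]  # AC, CD, DE each 1/3
#' @export
ggapVector <- function(seq, g) {
    res <- as.character(seq)[1]
    g <- as.integer(g)
    if (g < 0L) stop("g must be non-negative")
    r <- match(strsplit(res, "")[[1]], AA_ALPHABET20)
    if (anyNA(r)) stop("sequence contains non-standard residues")
    L <- length(r)
    npairs <- L - g - 1L
    if (npairs < 1L)
        stop("sequence of length ", L, " is too short for g = ", g,
             " (need L >= g + 2)")
    idx <- 20L * (r[seq_len(npairs)] - 1L) + (r[seq_len(npairs) + g + 1L] - 1L)
    v <- tabulate(idx + 1L, nbins = 400L) / npairs
    names(v) <- ggapFeatureNames(g)
    v
}

#' Build a g-gap feature matrix for a set of sequences
#'
#' Encodes every sequence at one gap value into a [GGapFeatureSet] (features
#' in rows, samples in columns, Bioconductor orientation). Sequences shorter
#' than g + 2 abort the run with all offending ids listed — samples are never
#' silently dropped, which would desynchronize the label vector.
#'
#' @param seqs `AAStringSet` (labels read from `mcols(seqs)$label` unless
#'   `labels` is given) or named character vector.
#' @param g Gap size.
#' @param labels Optional 0/1 label per sequence.
#' @return A [GGapFeatureSet] with 400 rows.
#' @export
ggapMatrix <- function(seqs, g, labels = NULL) {
    if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
    if (is.null(labels)) {
        labels <- S4Vectors::mcols(seqs)$label
        if (is.null(labels)) labels <- rep(NA_real_, length(seqs))
    }
    stopifnot(length(labels) == length(seqs))
    lens <- Biostrings::width(seqs)
    short <- lens < g + 2L
    if (any(short))
        stop("sequence(s) too short for g = ", g, ": ",
             paste(names(seqs)[short], collapse = ", "))
    vals <- vapply(as.character(seqs), function(s) unname(ggapVector(s, g)),
                   numeric(400L))
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    colnames(vals) <- ids
    newGGapFeatureSet(vals, g = rep(as.integer(g), 400L),
                      labels = as.numeric(labels))
}

## Internal constructor: values is features x samples.
newGGapFeatureSet <- function(values, g, labels,
                              first = NULL, second = NULL) {
    pairs <- expand.grid(second = AA_ALPHABET20, first = AA_ALPHABET20,
                         stringsAsFactors = FALSE)[, c("first", "second")]
    if (is.null(first)) {   # full 400-block per g value assumed
        blocks <- length(g) / 400L
        stopifnot(blocks == round(blocks))
        first <- rep(pairs$first, blocks)
        second <- rep(pairs$second, blocks)
    }
    rd <- S4Vectors::DataFrame(
        g = as.integer(g), first = first, second = second,
        dipIndex = dipeptideIndex(first, second))
    rownames(values) <- paste0("g", rd$g, "_", rd$first, rd$second)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(freq = values), rowData = rd,
        colData = S4Vectors::DataFrame(label = labels,
                                       row.names = colnames(values)))
    new("GGapFeatureSet", se)
}

#' Fuse selected per-g feature subsets into one matrix
#'
#' Concatenates, in ascending g order, the columns each per-g selection names
#' — preserving each selection's internal (ranked) order — into a single
#' [GGapFeatureSet]. Descriptors retain their (g, dipeptide) provenance, so
#' downstream rankings can be traced back. With the ten optimal subsets of
#' the standard benchmark protocol the fused width is 1266.
#'
#' @param matrices List of single-g [GGapFeatureSet] objects, ascending g,
#'   identical sample order.
#' @param selections List (parallel to `matrices`) of 1-based row indices to
#'   keep from each matrix, in ranked order. Duplicate indices within one g
#'   are an error.
#' @return A fused [GGapFeatureSet] of width `sum(lengths(selections))`.
#' @export
fuseMatrices <- function(matrices, selections) {
    stopifnot(length(matrices) == length(selections))
    ids <- colnames(matrices[[1]])
    labs <- SummarizedExperiment::colData(matrices[[1]])$label
    parts <- vector("list", length(matrices))
    for (i in seq_along(matrices)) {
        m <- matrices[[i]]
        if (!identical(colnames(m), ids))
            stop("matrices disagree on sample ids/order")
        sel <- as.integer(selections[[i]])
        if (length(sel) == 0L) next
        if (anyDuplicated(sel))
            stop("duplicate feature index within one g selection")
        if (any(sel < 1L | sel > nrow(m)))
            stop("selection index out of range for matrix ", i)
        parts[[i]] <- m[sel, ]
    }
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) == 0L) stop("all selections are empty")
    vals <- do.call(rbind, lapply(parts, function(p)
        SummarizedExperiment::assay(p, "freq")))
    rd <- do.call(rbind, lapply(parts, SummarizedExperiment::rowData))
    newGGapFeatureSet(vals, g = rd$g, labels = labs,
                      first = rd$first, second = rd$second)
}

#' @describeIn featureValues Samples x features frequency matrix.
#' @export
setMethod("featureValues", "GGapFeatureSet", function(x)
    t(SummarizedExperiment::assay(x, "freq")))

#' @describeIn sampleLabels Per-sample 0/1 class labels.
#' @export
setMethod("sampleLabels", "GGapFeatureSet", function(x)
    SummarizedExperiment::colData(x)$label)

#' Export a feature matrix as TSV
#'
#' Tab-separated values, one row per sample: first column `sample`, then one
#' column per descriptor named `g{g}_{XY}`.
#'
#' @param x A [GGapFeatureSet].
#' @param path Output path.
#' @export
writeFeatureTSV <- function(x, path) {
    m <- featureValues(x)
    df <- data.frame(sample = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
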