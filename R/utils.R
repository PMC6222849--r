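## Internal helpers shared across modules.

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All randomized operations in the package route their seed through this so
## identical inputs give bit-identical outputs.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Population standard deviation (divisor n, not n - 1).
popSd <- function(x) sqrt(mean((x - mean(x))^2))

## Coerce a feature container to the samples x features numeric matrix the
## selection and classification code operates on.
asSampleMatrix <- function(X) {
    if (is(X, "GGapFeatureSet"))
        t(SummarizedExperiment::assay(X, "freq"))
    else if (is.matrix(X))
        X
    else
        stop("expected a GGapFeatureSet or a samples x features matrix")
}

## Extract 0/1 labels from a container or pass a vector through, validated.
asBinaryLabels <- function(y) {
    if (is(y, "GGapFeatureSet"))
        y <- SummarizedExperiment::colData(y)$label
    y <- as.numeric(y)
    if (anyNA(y) || !all(y %in% c(0, 1)))
        stop("labels must be 0/1 with no missing values")
    y
}
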