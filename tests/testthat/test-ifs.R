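test_that("stratified folds balance both classes and are deterministic", {
    y <- rep(c(1, 0), each = 10)
    f <- stratifiedFolds(y, 5, seed = 3)
    tab <- table(f, y)
    expect_true(all(tab == 2))
    expect_identical(f, stratifiedFolds(y, 5, seed = 3))
    expect_false(identical(f, stratifiedFolds(y, 5, seed = 4)))

    # benchmark-shaped class sizes: per-fold counts differ by at most one
    yb <- rep(c(1, 0), c(99, 208))
    fb <- stratifiedFolds(yb, 5, seed = 1)
    tb <- table(fb, yb)
    expect_true(all(tb[, "1"] %in% c(19, 20)))
    expect_true(all(tb[, "0"] %in% c(41, 42)))
    expect_error(stratifiedFolds(c(1, 1, 1, 0, 0, 0), 4, 1), "fewer samples")
})

makeClouds <- function(n = 60, sd = 0.05, seed = 9) {
    withr::with_seed(seed, {
        y <- rep(c(0, 1), each = n / 2)
        X <- matrix(rnorm(n * 5, mean = rep(2 * y - 1, 5), sd = sd), n, 5)
        list(X = X, y = y)
    })
}

test_that("cross-validated SVM separates clear clouds and is at chance on permuted labels", {
    d <- makeClouds()
    cfg <- modelConfig(C = 1, gamma = 0.25, nFolds = 5L, seed = 11L)
    rep1 <- cvAccuracy(d$X, d$y, cfg)
    expect_equal(rep1@acc, 1)
    expect_equal(sum(confusionCounts(rep1)), 60)
    expect_equal(rep1@auroc, 1)

    yPerm <- withr::with_seed(21, sample(d$y))
    repNull <- cvAccuracy(d$X, yPerm, cfg)
    expect_gte(repNull@acc, 0.35)
    expect_lte(repNull@acc, 0.65)
})

test_that("grid search is exhaustive with smaller-C/gamma tie-breaking", {
    d <- makeClouds()
    one <- modelConfig(nFolds = 5L, seed = 2L, gridC = 8, gridGamma = 0.5)
    g1 <- gridSearch(d$X, d$y, one)
    expect_equal(c(g1$C, g1$gamma), c(8, 0.5))

    multi <- modelConfig(nFolds = 5L, seed = 2L, gridC = c(1, 4, 16),
                         gridGamma = c(0.125, 0.5))
    gm <- gridSearch(d$X, d$y, multi)
    expect_equal(gm$acc, 1)
    # separable data: several points tie at Acc 1; smallest C, then smallest
    # gamma must be returned
    expect_equal(c(gm$C, gm$gamma), c(1, 0.125))
})

test_that("IFS curves have the documented shape and prefix consistency", {
    d <- makeClouds(n = 40)
    # prepend a perfectly separating feature; remaining columns are noise
    X <- cbind(d$y + rnorm(40, sd = 1e-3), matrix(rnorm(40 * 4), 40, 4))
    cfg <- modelConfig(C = 4, gamma = 0.5, nFolds = 5L, seed = 5L)
    curve <- ifsSweep(X, d$y, cfg, maxK = 5, tune = "none")
    expect_equal(length(curve@sizes), 5L)
    expect_equal(curve@accuracies[1], 1)
    expect_equal(peakK(curve), 1L)
    expect_equal(accuracies(curve)[["5"]],
                 cvAccuracy(X, d$y, cfg)@acc)
    # identical inputs and seeds give bit-identical curves
    curve2 <- ifsSweep(X, d$y, cfg, maxK = 5, tune = "none")
    expect_identical(accuracies(curve), accuracies(curve2))
    expect_error(ifsSweep(X, d$y, cfg, maxK = 9), "exceeds")
})

test_that("pooled confusion counts always sum to the sample count", {
    d <- makeClouds(n = 30, sd = 1.5, seed = 77)
    cfg <- modelConfig(C = 2, gamma = 0.2, nFolds = 3L, seed = 8L)
    curve <- ifsSweep(d$X, d$y, cfg, maxK = 3, tune = "none")
    expect_equal(sum(confusionCounts(peakMetrics(curve))), 30)
})
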