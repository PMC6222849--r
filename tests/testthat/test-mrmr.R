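test_that("mean/sd discretization reproduces the worked 3-bin example", {
    d <- discretizeFeatures(cbind(x = c(0, 0, 0, 0, 10)))
    # mu = 2, population sigma = 4: edges at -2 and 6
    expect_equal(d@boundaries[[1]], c(-2, 6))
    expect_equal(unname(d@codes[, 1]), c(1L, 1L, 1L, 1L, 2L))

    dc <- discretizeFeatures(cbind(const = rep(3, 8)))
    expect_equal(unique(as.vector(dc@codes)), 0L)

    # relabeling invariance: MI with labels unchanged vs raw categories
    y <- c(0, 1, 0, 1, 0, 1, 1, 0)
    xb <- c(0, 1, 0, 1, 0, 1, 0, 1)
    db <- discretizeFeatures(cbind(xb))
    expect_equal(mutualInformation(db@codes[, 1], y),
                 mutualInformation(xb, y))
    expect_error(discretizeFeatures(cbind(xb), nBins = 1L), "at least 2")
})

test_that("mutual information matches direct summation and entropy identities", {
    x <- rep(0:1, each = 50)
    expect_equal(mutualInformation(x, x), 1)
    expect_equal(mutualInformation(rep(7, 30), rbinom(30, 1, 0.5)), 0)
    # joint counts (0,0)x2 (0,1)x1 (1,0)x1 (1,1)x2 over 6 samples
    a <- c(0, 0, 0, 1, 1, 1); b <- c(0, 0, 1, 0, 1, 1)
    expect_equal(mutualInformation(a, b),
                 (2 / 3) * log2(4 / 3) + (1 / 3) * log2(2 / 3),
                 tolerance = 1e-12)
    expect_error(mutualInformation(1:3, 1:4), "equal length")
})

test_that("MI is symmetric, non-negative, relabel-invariant; I(a,a) = H(a)", {
    withr::with_seed(303, {
        for (i in 1:20) {
            a <- sample(0:2, 40, replace = TRUE)
            b <- sample(0:3, 40, replace = TRUE)
            expect_equal(mutualInformation(a, b), mutualInformation(b, a),
                         tolerance = 1e-12)
            expect_gte(mutualInformation(a, b), 0)
            # permute category labels of a
            relab <- c(5L, 9L, 2L)[a + 1L]
            expect_equal(mutualInformation(relab, b),
                         mutualInformation(a, b), tolerance = 1e-12)
            expect_equal(mutualInformation(a, a), oracleEntropy(a),
                         tolerance = 1e-12)
            expect_equal(mutualInformation(a, b), oracleMI(a, b),
                         tolerance = 1e-12)
        }
    })
})

test_that("greedy mRMR starts at max relevance and demotes duplicated columns", {
    withr::with_seed(404, {
        y <- rep(c(0, 1), each = 15)
        strong <- y; strong[c(1, 16)] <- 1 - strong[c(1, 16)]
        weak <- c(rbinom(15, 1, 0.3), rbinom(15, 1, 0.7))
        codes <- cbind(strong = strong, copy = strong, weak = weak)
        rk <- mrmrOrder(codes, y, criterion = "mid")
        rel <- c(mutualInformation(strong, y), mutualInformation(strong, y),
                 mutualInformation(weak, y))
        expect_equal(rankOrder(rk)[1], which.max(rel))
        # the identical copy must not be picked second: its step-2 MID
        # criterion rel - I(x;x) is non-positive (data-processing bound)
        expect_false(rankOrder(rk)[2] == 2L)
        expect_lte(rel[2] - mutualInformation(strong, strong), 0)
    })
})

test_that("greedy order equals a brute-force oracle (MID and MIQ) and prefixes nest", {
    withr::with_seed(505, {
        n <- 50
        y <- rbinom(n, 1, 0.5)
        codes <- sapply(1:6, function(j) {
            noisy <- ifelse(runif(n) < 0.35, sample(0:2, n, TRUE), y)
            as.integer(noisy)
        })
        for (crit in c("mid", "miq")) {
            got <- rankOrder(mrmrOrder(codes, y, criterion = crit))
            expect_equal(got, oracleMrmr(codes, y, 6, criterion = crit))
        }
        full <- rankOrder(mrmrOrder(codes, y, m = 6))
        expect_setequal(full, 1:6)
        expect_equal(rankOrder(mrmrOrder(codes, y, m = 3)), full[1:3])
        expect_error(mrmrOrder(codes, y, m = 7), "m must lie")
    })
})

test_that("Z-scores standardize with the population sigma", {
    z <- zScores(c(1, 2, 3))
    expect_equal(z$z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
    expect_equal(z$z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
    expect_equal(mean(z$z), 0)
    expect_equal(sqrt(mean(z$z^2)), 1, tolerance = 1e-12)
    expect_equal(zScores(z$z)$z, z$z, tolerance = 1e-12)  # idempotent
    expect_error(zScores(rep(2, 5)), "zero variance")
    expect_error(zScores(3), "at least 2")
})
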