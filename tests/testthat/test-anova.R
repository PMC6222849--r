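test_that("F decomposition matches the hand-worked two-group example", {
    X <- cbind(f = c(1, 2, 3, 4, 5, 6))
    res <- anovaFScores(X, c(0, 0, 0, 1, 1, 1))
    expect_equal(res@ssBetween, 13.5)
    expect_equal(res@ssWithin, 4)
    expect_equal(res@dfBetween, 1L)
    expect_equal(res@dfWithin, 4L)
    expect_equal(unname(fScores(res)), 13.5)
    # same number out of R's standard one-way ANOVA
    expect_equal(unname(fScores(res)),
                 unname(oracleAnovaF(X, c(0, 0, 0, 1, 1, 1))),
                 tolerance = 1e-12)
})

test_that("degenerate features get the documented sentinels", {
    y <- c(0, 0, 0, 1, 1, 1)
    X <- cbind(constant = rep(2, 6),
               equalMeans = c(1, 2, 3, 3, 2, 1),
               separating = c(0, 0, 0, 1, 1, 1))
    f <- fScores(anovaFScores(X, y))
    expect_equal(unname(f["constant"]), 0)
    expect_equal(unname(f["equalMeans"]), 0)
    expect_equal(unname(f["separating"]), Inf)
    expect_error(anovaFScores(X, rep(0, 6)), "two groups")
    expect_error(anovaFScores(X[1:3, ], c(0, 1, 2)), "more samples")
})

test_that("F matches the standard one-way ANOVA on random matrices (2 and 3 groups)", {
    withr::with_seed(101, {
        for (rep in 1:25) {
            n <- sample(12:40, 1)
            p <- 4
            m <- matrix(rnorm(n * p), n, p)
            y2 <- sample(rep(c(0, 1), c(floor(n * 0.4), n - floor(n * 0.4))))
            expect_equal(unname(fScores(anovaFScores(m, y2))),
                         unname(oracleAnovaF(m, y2)), tolerance = 1e-9)
            y3 <- sample(rep(letters[1:3], length.out = n))
            expect_equal(unname(fScores(anovaFScores(m, y3))),
                         unname(oracleAnovaF(m, y3)), tolerance = 1e-9)
        }
    })
})

test_that("F is affine- and permutation-invariant, and SS decomposes totals", {
    withr::with_seed(202, {
        n <- 30
        m <- matrix(rnorm(n * 5), n, 5)
        y <- rep(c(0, 1), c(12, 18))
        base <- anovaFScores(m, y)
        # affine transform a*x + b leaves F unchanged
        scaled <- sweep(sweep(m, 2, runif(5, 0.5, 3), "*"), 2, rnorm(5), "+")
        expect_equal(fScores(anovaFScores(scaled, y)), fScores(base),
                     tolerance = 1e-9)
        # permuting samples (with their labels) leaves F unchanged
        perm <- sample(n)
        expect_equal(fScores(anovaFScores(m[perm, ], y[perm])),
                     fScores(base), tolerance = 1e-9)
        # SS_B + SS_W = total SS about the grand mean
        sst <- colSums(sweep(m, 2, colMeans(m))^2)
        expect_equal(base@ssBetween + base@ssWithin, unname(sst),
                     tolerance = 1e-9)
    })
})

test_that("ranking is descending with stable index tie-breaks", {
    expect_equal(rankOrder(rankByScore(c(0.1, 5.0, 2.0))), c(2L, 3L, 1L))
    expect_equal(rankOrder(rankByScore(c(3.0, 3.0, 1.0))), c(1L, 2L, 3L))
    expect_equal(rankOrder(rankByScore(rep(1, 4))), 1:4)
    rk <- rankByScore(c(a = 1, b = Inf, c = 2))
    expect_equal(rankOrder(rk), c(2L, 3L, 1L))
    expect_equal(rk@descriptors$name, c("b", "c", "a"))
})
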