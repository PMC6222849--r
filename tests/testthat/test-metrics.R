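test_that("threshold metrics reproduce the benchmark confusion arithmetic", {
    r <- confusionMetrics(tp = 83, fn = 16, fp = 21, tn = 187)
    expect_equal(r@acc, 270 / 307)
    expect_equal(r@sn, 83 / 99)
    expect_equal(r@sp, 187 / 208)
    expect_equal(sprintf("%.2f", 100 * c(r@sn, r@sp, r@acc)),
                 c("83.84", "89.90", "87.95"))
    # the Mcc this confusion matrix actually implies
    expect_equal(r@mcc, (83 * 187 - 21 * 16) /
                     sqrt(prod(c(104, 99, 208, 203))), tolerance = 1e-12)
    expect_equal(round(r@mcc, 3), 0.728)
})

test_that("perfect and degenerate classifiers follow the conventions", {
    perfect <- confusionMetrics(10, 0, 0, 10)
    expect_equal(c(perfect@sn, perfect@sp, perfect@acc, perfect@mcc),
                 c(1, 1, 1, 1))
    degen <- confusionMetrics(0, 10, 0, 10)
    expect_equal(degen@mcc, 0)
    expect_equal(degen@acc, 0.5)
    expect_error(confusionMetrics(0, 0, 0, 0), "empty")
})

test_that("Mcc identities: swap symmetry, negation, and weighted Acc bound", {
    withr::with_seed(606, {
        for (i in 1:20) {
            cm <- rmultinom(1, 60, c(0.3, 0.2, 0.2, 0.3))[, 1] + 1
            a <- confusionMetrics(cm[1], cm[2], cm[3], cm[4])
            swapped <- confusionMetrics(cm[4], cm[3], cm[2], cm[1])
            expect_equal(swapped@mcc, a@mcc, tolerance = 1e-12)
            inverted <- confusionMetrics(cm[2], cm[1], cm[4], cm[3])
            expect_equal(inverted@mcc, -a@mcc, tolerance = 1e-12)
            # Acc is the class-size-weighted mean of Sn and Sp
            nP <- cm[1] + cm[2]; nN <- cm[3] + cm[4]
            expect_equal(a@acc, (nP * a@sn + nN * a@sp) / (nP + nN),
                         tolerance = 1e-12)
        }
    })
})

test_that("ROC sweep handles ordered, anti-ordered and tied scores", {
    expect_equal(rocCurve(c(4, 3, 2, 1), c(1, 1, 0, 0))$auroc, 1)
    expect_equal(rocCurve(c(1, 2, 3, 4), c(1, 1, 0, 0))$auroc, 0)
    rc <- rocCurve(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
    expect_equal(rc$auroc, 0.75)
    expect_equal(rc$points[1, ], c(fpr = 0, tpr = 0))
    expect_equal(rc$points[nrow(rc$points), ], c(fpr = 1, tpr = 1))
    # all scores tied: the curve is the diagonal
    expect_equal(rocCurve(rep(1, 10), rep(c(0, 1), 5))$auroc, 0.5)
    expect_error(rocCurve(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("trapezoidal auROC equals Mann-Whitney pair counting exactly", {
    withr::with_seed(707, {
        for (i in 1:15) {
            n <- sample(20:200, 1)
            labels <- rbinom(n, 1, 0.4)
            if (length(unique(labels)) < 2) next
            # coarse scores force plenty of ties
            scores <- round(rnorm(n), sample(0:1, 1))
            expect_equal(rocCurve(scores, labels)$auroc,
                         oracleAuroc(scores, labels), tolerance = 1e-12)
        }
    })
})

test_that("auROC agrees with an established ROC implementation", {
    skip_if_not_installed("pROC")
    withr::with_seed(808, {
        labels <- rbinom(120, 1, 0.35)
        scores <- rnorm(120) + labels
        expect_equal(rocCurve(scores, labels)$auroc,
                     as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                    quiet = TRUE,
                                                    direction = "<"))),
                     tolerance = 1e-12)
    })
})
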