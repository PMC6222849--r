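test_that("dipeptide indexing is the alphabetical row-major bijection", {
    expect_equal(dipeptideIndex("A", "A"), 0L)
    expect_equal(dipeptideIndex("A", "C"), 1L)
    expect_equal(dipeptideIndex("Y", "Y"), 399L)
    all400 <- expand.grid(second = AA_ALPHABET20, first = AA_ALPHABET20)
    idx <- dipeptideIndex(as.character(all400$first),
                          as.character(all400$second))
    expect_setequal(idx, 0:399)
    expect_error(dipeptideIndex("A", "X"), "X")
})

test_that("g-gap vectors match hand-computed frequencies", {
    v <- ggapVector("ACDE", 0)
    expect_equal(unname(v[c("g0_AC", "g0_CD", "g0_DE")]), rep(1 / 3, 3))
    expect_equal(sum(v), 1)
    expect_equal(sum(v > 0), 3)

    v1 <- ggapVector("AAAA", 1)
    expect_equal(unname(v1["g1_AA"]), 1)
    expect_equal(sum(v1), 1)

    expect_error(ggapVector("AC", 1), "too short")
})

test_that("g-gap vectors sum to 1 and agree with pair-enumeration oracle", {
    seqs <- randomSeqs(12, 15:60, seed = 42)
    for (g in c(0, 1, 3, 9)) {
        for (s in seqs) {
            v <- ggapVector(s, g)
            expect_equal(sum(v), 1, tolerance = 1e-12)
            counts <- oraclePairCounts(s, g)
            expect_equal(sum(counts), nchar(s) - g - 1)
            expect_equal(unname(v), unname(counts / (nchar(s) - g - 1)))
        }
    }
    # g = 0 equals the classical adjacent-dipeptide composition
    expect_equal(unname(ggapVector(seqs[1], 0)), oracleBigramFreq(seqs[1]))
})

test_that("feature matrices align with input order and never drop samples silently", {
    seqs <- c(a = "ACDEFGHIKL", b = "MNPQRSTVWY")
    X <- ggapMatrix(seqs, 0, labels = c(1, 0))
    expect_s4_class(X, "GGapFeatureSet")
    expect_equal(dim(featureValues(X)), c(2L, 400L))
    expect_equal(unname(rowSums(featureValues(X))), c(1, 1))
    expect_equal(sampleLabels(X), c(1, 0))
    expect_false(identical(featureValues(ggapMatrix(seqs, 0, c(1, 0))),
                           featureValues(ggapMatrix(seqs, 1, c(1, 0)))))
    expect_error(ggapMatrix(c(long = "ACDEFGHIKL", tiny = "AC"), 2, c(1, 0)),
                 "tiny")
})

test_that("fusion concatenates selections in ascending g with provenance kept", {
    seqs <- randomSeqs(3, 30:40, seed = 7)
    mats <- lapply(0:9, function(g) ggapMatrix(seqs, g, labels = c(1, 0, 1)))

    # subset sizes of the standard benchmark protocol fuse to width 1266
    sizes <- c(107, 213, 135, 87, 42, 89, 70, 174, 255, 94)
    sels <- lapply(sizes, seq_len)
    fused <- fuseMatrices(mats, sels)
    expect_equal(nrow(fused), 1266L)
    expect_equal(sum(sizes), 1266)
    rd <- SummarizedExperiment::rowData(fused)
    expect_equal(as.integer(table(rd$g)), sizes)
    expect_false(is.unsorted(rd$g))

    # identity case: only g = 0 contributes
    sels0 <- c(list(c(5L, 2L, 9L)), rep(list(integer(0)), 9))
    f0 <- fuseMatrices(mats, sels0)
    expect_equal(SummarizedExperiment::assay(f0, "freq"),
                 SummarizedExperiment::assay(mats[[1]], "freq")[c(5, 2, 9), ])

    expect_error(fuseMatrices(mats[1], list(c(1L, 1L))), "duplicate")
    bad <- ggapMatrix(c(x = "ACDEFGHIKL"), 0, labels = 1)
    expect_error(fuseMatrices(list(mats[[1]], bad), list(1L, 1L)),
                 "sample")
})

test_that("encoding depends only on residues and g, not on ids", {
    a <- ggapVector(c(id1 = "ACDEACDE"), 2)
    b <- ggapVector(c(other = "ACDEACDE"), 2)
    expect_equal(unname(a), unname(b))
})
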