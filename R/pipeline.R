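#' Stage 1: per-gap ANOVA ranking and incremental feature selection
#'
#' For every gap value g the sequences are encoded as 400-dimensional g-gap
#' dipeptide matrices, features are ranked by ANOVA F, and an IFS sweep with
#' a cross-validated RBF-SVM locates the optimal prefix. The per-g optimal
#' subsets (ranked feature indices up to the accuracy peak) are the input to
#' stage 2.
#'
#' @param pos,neg `AAStringSet`s (or named character vectors) of positive
#'   (virion) and negative sequences.
#' @param gRange Integer vector of gap values (default 0..9).
#' @param config A [ModelConfig].
#' @param maxK Largest IFS prefix per g (default: all 400; cap it for
#'   desk-scale runs).
#' @param kStep Stride of the IFS sweep.
#' @param tune Tuning mode passed to [ifsSweep()].
#' @param outDir Optional directory: per-g rankings, curves and the subset
#'   table are written as TSV.
#' @return List with `perG` (per-g list of `g`, `ranking`, `curve`,
#'   `selection`), `matrices` (per-g [GGapFeatureSet]), and `labels`.
#' @export
runStage1 <- function(pos, neg, gRange = 0:9, config = modelConfig(),
                      maxK = 400L, kStep = 1L, tune = "once",
                      outDir = NULL) {
    if (is.character(pos)) pos <- Biostrings::AAStringSet(pos)
    if (is.character(neg)) neg <- Biostrings::AAStringSet(neg)
    seqs <- c(pos, neg)
    labels <- c(rep(1, length(pos)), rep(0, length(neg)))
    perG <- list()
    matrices <- list()
    for (g in gRange) {
        X <- ggapMatrix(seqs, g, labels = labels)
        an <- anovaFScores(X, labels)
        rk <- rankByScore(fScores(an),
                          descriptors = SummarizedExperiment::rowData(X))
        mK <- min(maxK, 400L)
        Xr <- featureValues(X)[, rankOrder(rk)[seq_len(mK)], drop = FALSE]
        curve <- ifsSweep(Xr, labels, config, maxK = mK, kStep = kStep,
                          tune = tune)
        sel <- rankOrder(rk)[seq_len(peakK(curve))]
        perG[[as.character(g)]] <- list(g = g, ranking = rk, curve = curve,
                                        selection = sel)
        matrices[[as.character(g)]] <- X
        if (!is.null(outDir)) {
            if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
            writeRankingTSV(rk, file.path(outDir, sprintf("anova_g%d.tsv", g)))
            writeCurveTSV(curve, file.path(outDir, sprintf("ifs_g%d.tsv", g)))
        }
    }
    if (!is.null(outDir)) {
        sizes <- vapply(perG, function(p) length(p$selection), integer(1))
        utils::write.table(
            data.frame(g = as.integer(names(perG)), nFeatures = sizes,
                       acc = vapply(perG, function(p)
                           max(p$curve@accuracies), numeric(1))),
            file.path(outDir, "stage1_subsets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(perG = perG, matrices = matrices, labels = labels)
}

#' Stage 2: fusion, mRMR re-ranking, final IFS and model
#'
#' Fuses the per-g optimal subsets from [runStage1()] into one matrix,
#' discretizes it, orders the fused features by the greedy mRMR criterion,
#' sweeps prefixes of that order with the cross-validated SVM, and trains
#' the final model on all samples at the peak with the tuned (C, gamma).
#' mRMR step scores are standardized to Z-scores for reporting.
#'
#' @param stage1 Output of [runStage1()].
#' @param config A [ModelConfig].
#' @param criterion `"mid"` or `"miq"` mRMR variant.
#' @param nBins,scheme,width Passed to [discretizeFeatures()].
#' @param maxK Largest prefix of the mRMR order swept (default: all fused
#'   features).
#' @param kStep,tune Passed to [ifsSweep()].
#' @param outDir Optional directory for TSV/ROC/model outputs.
#' @return List with `fused` ([GGapFeatureSet]), `mrmr` ([RankedFeatures]),
#'   `z` (Z-scored mRMR step scores), `curve` ([IFSCurve]), `metrics`
#'   ([MetricsReport] at the peak), and `bundle` (the deployable model:
#'   svm fit, selected descriptors, C, gamma, version).
#' @export
runStage2 <- function(stage1, config = modelConfig(), criterion = "mid",
                      nBins = 3L, scheme = "meansd", width = 1,
                      maxK = NULL, kStep = 1L, tune = "once",
                      outDir = NULL) {
    sels <- lapply(stage1$perG, `[[`, "selection")
    fused <- fuseMatrices(stage1$matrices, sels)
    y <- stage1$labels
    Xd <- discretizeFeatures(fused, nBins = nBins, scheme = scheme,
                             width = width)
    rk <- mrmrOrder(Xd, y, criterion = criterion,
                    descriptors = SummarizedExperiment::rowData(fused))
    z <- zScores(rankScores(rk))
    if (is.null(maxK)) maxK <- length(rankOrder(rk))
    Xr <- featureValues(fused)[, rankOrder(rk)[seq_len(maxK)], drop = FALSE]
    curve <- ifsSweep(Xr, y, config, maxK = maxK, kStep = kStep, tune = tune)
    k <- peakK(curve)
    pars <- curve@params[curve@params$k == k, ]
    selIdx <- rankOrder(rk)[seq_len(k)]
    desc <- SummarizedExperiment::rowData(fused)[selIdx, , drop = FALSE]
    fit <- e1071::svm(x = featureValues(fused)[, selIdx, drop = FALSE],
                      y = factor(y, levels = c(0, 1)), kernel = "radial",
                      cost = pars$C[1], gamma = pars$gamma[1], scale = FALSE)
    bundle <- list(format = "virionPred-model-1", model = fit,
                   descriptors = as.data.frame(desc),
                   C = pars$C[1], gamma = pars$gamma[1],
                   nFeatures = k)
    if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        writeFeatureTSV(fused, file.path(outDir, "fused_matrix.tsv"))
        writeRankingTSV(rk, file.path(outDir, "mrmr_ranking.tsv"),
                        extra = list(zscore = z$z))
        writeCurveTSV(curve, file.path(outDir, "ifs_mrmr.tsv"))
        writeMetricsTSV(peakMetrics(curve),
                        file.path(outDir, "metrics.tsv"),
                        rocPath = file.path(outDir, "roc.tsv"))
        saveRDS(bundle, file.path(outDir, "model_bundle.rds"))
    }
    list(fused = fused, mrmr = rk, z = z, curve = curve,
         metrics = peakMetrics(curve), bundle = bundle)
}

#' Run the complete two-step pipeline
#'
#' Convenience wrapper: [runStage1()] then [runStage2()].
#'
#' @inheritParams runStage1
#' @inheritParams runStage2
#' @param maxKStage1,maxKStage2 Prefix caps for the two IFS sweeps.
#' @return The [runStage2()] result with the stage-1 output attached as
#'   `$stage1`.
#' @export
runPipeline <- function(pos, neg, gRange = 0:9, config = modelConfig(),
                        maxKStage1 = 400L, maxKStage2 = NULL,
                        kStep = 1L, tune = "once", criterion = "mid",
                        outDir = NULL) {
    s1 <- runStage1(pos, neg, gRange = gRange, config = config,
                    maxK = maxKStage1, kStep = kStep, tune = tune,
                    outDir = outDir)
    s2 <- runStage2(s1, config = config, criterion = criterion,
                    maxK = maxKStage2, kStep = kStep, tune = tune,
                    outDir = outDir)
    s2$stage1 <- s1
    s2
}

#' Predict virion class for new sequences with a trained model bundle
#'
#' Encodes only the descriptors the model selected (so only the gap values
#' it uses), scores each sequence with the stored SVM, and returns a table
#' of id, decision score, and predicted label. Sequences too short for a
#' required gap are reported together in one error.
#'
#' @param bundle Model bundle from [runStage2()].
#' @param seqs `AAStringSet` or named character vector. Empty input gives an
#'   empty table with a warning.
#' @return data.frame with columns `id`, `score`, `label`.
#' @export
predictProteins <- function(bundle, seqs) {
    if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
    if (length(seqs) == 0L) {
        warning("no sequences to predict")
        return(data.frame(id = character(0), score = numeric(0),
                          label = integer(0)))
    }
    desc <- bundle$descriptors
    gs <- sort(unique(desc$g))
    lens <- Biostrings::width(seqs)
    short <- lens < max(gs) + 2L
    if (any(short))
        stop("sequence(s) too short for the model's largest gap (g = ",
             max(gs), "): ", paste(names(seqs)[short], collapse = ", "))
    X <- matrix(0, nrow = length(seqs), ncol = nrow(desc))
    chars <- as.character(seqs)
    for (g in gs) {
        rows <- which(desc$g == g)
        vg <- vapply(chars, function(s) unname(ggapVector(s, g)),
                     numeric(400L))          # 400 x nseq
        X[, rows] <- t(vg[desc$dipIndex[rows] + 1L, , drop = FALSE])
    }
    pr <- stats::predict(bundle$model, X, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    score <- dv[, 1]
    if (sub("/.*", "", colnames(dv)[1]) == "0") score <- -score
    data.frame(id = names(seqs), score = unname(score),
               label = as.integer(as.character(pr)), row.names = NULL)
}
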