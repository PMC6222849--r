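# virionPred

Sequence-based identification of **phage virion (structural) proteins** —
capsid, envelope and particle enzymes packaged into the mature
bacteriophage — versus non-structural phage proteins, from the amino-acid
sequence alone.

The method is a two-step feature-selection cascade over **g-gap dipeptide
compositions** feeding an RBF-kernel SVM:

1. For each gap g = 0..9, a protein of length L is encoded by the
   frequencies of the 400 ordered residue pairs at offset g + 1,
   `v_i^g = n_i^g / (L − g − 1)`. Features are ranked per gap by the
   one-way ANOVA F statistic `F = (SS_B/df_B)/(SS_W/df_W)`, and incremental
   feature selection (IFS) — evaluating nested prefixes of the ranking with
   a cross-validated SVM — finds each gap's optimal subset.
2. The ten optimal subsets are fused into one vector, re-ordered by greedy
   **mRMR** (maximal mutual information with the class, minimal mean mutual
   information with already-selected features, on 3-bin discretized
   values), and a second IFS pass locates the final model. Performance is
   reported as pooled five-fold cross-validation Sn, Sp, Acc, Mcc and
   auROC.

Because curated benchmark data cannot be shipped, the package includes a
deterministic synthetic-FASTA generator that plants g-gap dipeptide
signals at known gaps and enrichments, so the entire cascade is testable
offline, including parameter-recovery and null-calibration experiments.

## Worked example

```r
library(virionPred)

spec <- benchmarkShapeSpec(enrichment = 8, seed = 7)   # 99 pos / 208 neg
sets <- generateSequences(spec)

cfg <- modelConfig(nFolds = 5, seed = 7,
                   gridC = 2^c(-1, 3, 7), gridGamma = 2^c(-7, -3, 1))
res <- runPipeline(sets$pos, sets$neg, gRange = 0:9, config = cfg,
                   maxKStage1 = 25, kStep = 2, tune = "once")
res$metrics
#> MetricsReport  (TP 98 FN 1 FP 0 TN 208 )
#>   Sn 98.99%  Sp 100.00%  Acc 99.67%  Mcc 0.9926  auROC 0.9992
res$curve
#> IFSCurve: 116 prefix sizes, k = 1 .. 230
#>   peak: Acc 0.9967 at k = 119
```

The report reads: 98 of 99 planted-signal positives were recovered in
pooled five-fold cross-validation (Sn), no negatives were misclassified
(Sp), for an overall accuracy of 99.67% at the mRMR-IFS peak of 119 fused
features. (Synthetic planted signal at enrichment 8 is an easy problem by
design — the run demonstrates the machinery, not real-data accuracy.)

Score new sequences with the persisted model:

```r
predictProteins(res$bundle, sets$pos[1:2])
#>        id    score label
#> 1 pos_001 1.621374     1
#> 2 pos_002 2.721335     1
```

A thin command-line front-end is installed at
`system.file("exec", "virionpred", package = "virionPred")` with
subcommands `simulate`, `stage1`, `stage2`, `predict`, `evaluate`.

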