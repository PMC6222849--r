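---
title: "Two-step g-gap dipeptide feature selection for phage virion protein prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step g-gap dipeptide feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virionPred)
```

## The problem

Bacteriophage proteins split into structural (virion) proteins — capsid,
envelope and particle enzymes packaged into the mature phage — and
non-structural proteins expressed only during infection. Telling the two
apart from sequence alone is a binary classification problem with practical
value for phage biology and antimicrobial development, since experimental
assignment by mass spectrometry does not scale with sequence databases.

`virionPred` implements a complete sequence-based classifier for this
problem: g-gap dipeptide encoding, a two-step feature-selection cascade
(per-gap ANOVA-F filtering with incremental feature selection, then
fusion and a mutual-information re-ranking), and an RBF-kernel SVM
evaluated by pooled five-fold cross-validation.

## Encoding: g-gap dipeptide composition

A protein `P = A1 A2 ... AL` over the 20 standard amino acids is encoded,
for a gap value g, by the frequencies of all 400 ordered residue pairs
separated by exactly g intervening positions:

$$v_i^g = \frac{n_i^g}{L - g - 1}, \qquad i = 1, \dots, 400,$$

where $n_i^g$ counts occurrences of the i-th ordered pair at offset
g + 1. With g = 0 this is the classical adjacent dipeptide composition;
larger gaps capture residue correlations that can be adjacent in the folded
structure though not in sequence. Every encoded vector is non-negative and
sums to exactly 1 (there are exactly L − g − 1 such pairs), which the test
suite asserts against an independent pair-enumeration oracle. Sequences
shorter than g + 2 cannot be encoded at that gap; the package aborts with
the offending ids rather than dropping samples, because silent loss would
desynchronize the label vector. The ordering of the 400 pairs (alphabetical,
first residue major) is a free convention fixed so ranked outputs are
reproducible.

Residue validation is strict: records containing anything outside the
20-letter alphabet — ambiguity codes B, U, X, Z, or the stop character
`*` — are rejected by name at read time, mirroring the curation rule used
to build high-quality benchmark sets. Lowercase input is accepted and
uppercased, a common FASTA dialect difference rather than a data problem.

## Step 1: ANOVA-F filtering with incremental feature selection

With 400 features per gap and ten gap values there are far too many
subsets to search (the 400-feature space alone has
$\sum_{k=1}^{400}\binom{400}{k} = 2^{400}-1 \approx 2.58\times10^{120}$
non-empty subsets — `countFeatureSubsets(400)` computes this exactly).
Instead, each feature is scored by the one-way ANOVA F statistic

$$F(i) = \frac{SS_B(i)/(K-1)}{SS_W(i)/(M-K)},$$

the ratio of between-class to within-class variance (K = 2 classes,
M samples), used as a univariate relevance filter, not as a hypothesis
test — no p-values or multiplicity corrections enter the ranking. Features
are ranked by F descending, and incremental feature selection (IFS)
evaluates the nested prefixes of length k = 1, 2, ... with a
cross-validated SVM, taking the smallest k that maximizes accuracy. The
sweep covers the whole curve rather than stopping at the first dip, which
would halt on local plateaus.

Degenerate features need conventions the formulas do not supply: a feature
with zero within-class variance but distinct class means receives an
infinite score (a perfectly separating feature must rank first), and an
entirely constant feature (0/0) scores 0. Ties in F break toward the lower
feature index so rankings are reproducible.

## Step 2: fusion and mRMR re-ranking

The ten per-gap optimal subsets are fused — columns concatenated in
ascending g, each block in its F-ranked order — into one matrix (1266
features for the original benchmark's subset sizes). Because highly ranked
features can be mutually redundant, the fused set is re-ordered by greedy
minimal-redundancy-maximal-relevance (mRMR): features are first discretized
(three bins at mean ± one population standard deviation per feature, the
classical mRMR preprocessing; the multiplier and an equal-frequency
alternative are configurable), then mutual information

$$I(x, y) = \sum_{x,y} \hat p(x,y)\,\log_2\frac{\hat p(x,y)}{\hat p(x)\hat p(y)}$$

is estimated by plug-in empirical frequencies without pseudocounts. The
first feature maximizes relevance $I(x_i; c)$ to the class; each later pick
maximizes the incremental criterion — relevance minus mean redundancy to
the already-selected set (MID, the default) or their quotient (MIQ, with a
fallback to pure relevance when mean redundancy is below 1e−12). Logarithms
are base 2; the base rescales all scores uniformly and cannot change the
greedy order. The set-level objective is NP-hard, so the standard greedy
incremental form is used and is verified against a brute-force
re-implementation of the step rule in the tests. A second IFS pass over the
mRMR order locates the final model size, and mRMR step scores are
standardized ($Z_i = (x_i - \mu)/\sigma$, population $\sigma$) for
reporting.

## Classifier and evaluation

The classifier is a soft-margin SVM with RBF kernel (through `e1071`, an
interface to LibSVM). Features are already frequencies in [0, 1], so no
rescaling is applied. (C, γ) are tuned by exhaustive grid search —
defaults C ∈ {2⁻⁵, 2⁻³, …, 2¹⁵}, γ ∈ {2⁻¹⁵, …, 2³} — with ties resolved
toward the smaller C then the smaller γ. Cross-validation uses stratified
folds (per-class counts differ by at most one across folds) with a
deterministic assignment given the seed. Metrics are *pooled*: out-of-fold
predictions from all folds form a single confusion matrix and decision
score vector, from which sensitivity, specificity, accuracy, and the
Matthews correlation coefficient are computed, together with an ROC curve
whose thresholds descend through unique scores (tied blocks move together)
and whose trapezoidal area equals the Mann–Whitney pair-counting statistic
exactly. An Mcc whose denominator contains a zero factor is defined as 0.
Class imbalance is not reweighted.

Whether tuning should be repeated at every prefix size is genuinely open;
both are supported (`tune = "per-k"` for honest nested tuning,
`tune = "once"` to tune on the full prefix and reuse, `"none"` for fixed
parameters). `"once"` is the default for desk-scale work.

## The synthetic benchmark

Real curated benchmark data cannot be redistributed with the package, so a
generator produces labeled FASTA with known structure: negatives are drawn
i.i.d. from a background residue distribution (uniform by default, with a
Swiss-Prot-like preset for realism); positives use biased sequential
sampling — when the residue g + 1 positions back matches the first residue
of a planted (g, a, b) pair, the weight of b is multiplied by the
enrichment factor before renormalization. Planting during generation, as
opposed to editing sequences afterwards, keeps compositions natural and
the factor interpretable as a conditional enrichment. Generation is
deterministic given the seed, and an enrichment whose expected pair
frequency would exceed 1 is rejected.

`benchmarkShapeSpec()` reproduces the class imbalance of the original
curated benchmark (99 positives, 208 negatives, M = 307) with eight planted
pairs at gaps 0–2 and enrichment 8 by default; lengths are drawn from
80–200, a typical span for phage structural proteins and comfortably above
the g + 2 = 11 minimum for g = 9. Under a null specification (no
enrichment) the per-feature F statistics are calibrated: about 5% exceed
the F(1, 305) 95th percentile.

What passing synthetic tests does and does not show: the generator plants
first-order dipeptide biases only — no domains, no homology structure, no
length–class association — so recovery demonstrates that the machinery
finds the signal class it models, not that real phage proteomes are
predicted at any particular accuracy. Published headline numbers depend on
a curated dataset that cannot be reconstructed from summary statistics, and
are therefore not reproduction targets here.

## A note on selection bias

The protocol ranks and selects features on the full dataset and then
cross-validates the classifier — the same workflow as the published
method. The selection step sees the test folds, so pooled CV accuracy is an
optimistic estimate of generalization. The effect is visible in this
package's own control experiment: with labels permuted, the full
re-selection pipeline still reaches a pooled CV accuracy far above the
majority-class share (which, at 99/208 imbalance, is already 0.68). Users
who need unbiased estimates should wrap the entire pipeline in an outer
resampling loop, or evaluate once on held-out data via
`predictProteins()`; the per-record prediction path never touches the
selection machinery.

## Problem sizes and numerical choices

The test-suite and acceptance experiments run the full pipeline at the
benchmark shape (99/208) over g = 0..9 with the per-gap IFS capped at the
top 25 ranked features, a sweep stride of 2, and a 3 × 3 (C, γ) grid tuned
once per sweep — sizes chosen as a desk-scale configuration that leaves the
selection cascade's behavior intact. Unit-sum assertions use a 1e−12
absolute tolerance (encodings are exact rationals); ANOVA equivalence to
the standard one-way decomposition is asserted at 1e−9 relative error; the
auROC/Mann–Whitney identity is exact. Fold assignment, sequence generation
and label permutation all derive from explicit integer seeds, and identical
inputs with identical seeds give bit-identical outputs.

## Worked example

```{r example, eval = FALSE}
spec <- benchmarkShapeSpec(enrichment = 8, seed = 7)
sets <- generateSequences(spec)

cfg <- modelConfig(nFolds = 5, seed = 7,
                   gridC = 2^c(-1, 3, 7), gridGamma = 2^c(-7, -3, 1))
res <- runPipeline(sets$pos, sets$neg, gRange = 0:9, config = cfg,
                   maxKStage1 = 25, kStep = 2, tune = "once")
res$metrics
res$curve

pred <- predictProteins(res$bundle, sets$pos[1:3])
```

## Known limitations

* Greedy mRMR and IFS are heuristics; neither optimizes its set-level
  objective exactly.
* The discretization scheme and the MID/MIQ choice change the mRMR order;
  defaults follow the original mRMR literature, but no universally correct
  choice exists.
* Pooled CV with selection-before-CV overstates accuracy (see above).
* The generator models first-order dipeptide structure only.
* Very short sequences (L < g + 2) are unencodable at gap g and abort the
  run by design.
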