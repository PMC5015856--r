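---
title: "Methods: two-network classification of drug sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-network classification of drug sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. Nothing here reports a number that the test
suite or `scripts/acceptance.R` does not itself compute.

## The model

The classifier rests on one modelling assumption: the *co-expression
structure* of a gene panel differs between drug-sensitive and
drug-resistant cells, even where single-gene distributions do not. It
encodes each class as an undirected graph over a shared panel of `m'`
genes — an edge wherever the absolute Pearson correlation of two genes
across that class's training cell lines exceeds a threshold `ε` — and
equips every node with a regression function predicting its expression
from its neighbours' expression. A test profile is pushed through both
graphs; whichever class reconstructs it with smaller mean squared error,
`1/m' Σ_k (x_k − y_k)²`, is predicted. The classifier therefore never
outputs an "ambiguous" call (its balanced ambiguous rate is identically
zero); the ambiguous zone exists only in the EC50 labeling and in the
2 × 3 confusion matrices used to compare against regression-style
predictors that do predict a response value.

### Labeling

Cell lines are scored as `-log10(EC50 [M])`; EC50 inputs are in µM, hence
the `+6` term in the µM forms of the formulas. Clinical cutoffs anchor the
decision on the drug's average maximal plasma concentration `Cmax` (µM):
`resistant = -log10(Cmax·1.5) + 6`, `sensitive = -log10(Cmax/1.5) + 6`.
The factor 1.5 on either side of the clinical exposure makes the two
cutoffs differ by exactly `2·log10(1.5) ≈ 0.352` — an identity the test
suite checks and that curated cutoff tables reproduce up to printing
precision. Statistical cutoffs, for drugs without a trustworthy Cmax, are
`-log10(μ ± 0.3σ)` with `μ, σ` the mean and SD of the EC50 values.

Three decisions here were genuinely open:

* **µM vs log-scale moments.** Whether `μ` and `σ` are taken on EC50 in µM
  or on the `-log10` scores is not determined by the formulas alone; the
  µM reading is implemented (it is the only one on which `-log10(μ ± 0.3σ)`
  is well-formed as written, and it lands the statistical pairs on the
  same `+6` scale as the clinical ones).
* **SD convention.** Sample SD (n−1) is the default; population SD is one
  switch away (`sdType = "population"`). At the panel sizes involved the
  difference is far below the 3-decimal precision of published tables.
* **Clamp floor.** Published cutoff tables print `resistant = 5.000` for a
  few drugs whose Cmax-derived cutoff would fall below `-log10` of a
  10 µM maximal screened dose; `clinicalCutoffs()` therefore raises both
  values to a floor of 5 by default (`clampFloor = NULL` disables it).
* **Boundaries.** A score exactly equal to a cutoff is *ambiguous*:
  membership in either class requires a strict inequality.

Ambiguous cell lines are excluded from training and testing, and drugs
whose label distribution leaves fewer than `minPerClass` cell lines in
either class are excluded entirely (`filterBalancedDrugs()`).

### Feature selection

For each gene, the observed expression range is split into `t` equal-width
intervals; the last interval is closed so the maximum falls into term `t`,
and a constant gene maps everything to term 1. The 2 × t class-by-term
count matrix `A` is compared to its independence expectation
`E = n · P_class · P_term`, and `χ² = Σ (A−E)²/E` ranks the genes. Cells
with `E = 0` (empty terms) force `A = 0` and contribute zero — the natural
convention that avoids pseudo-counts. Ranking ties break lexicographically
by symbol so a selection is reproducible across platforms. `t` defaults to
10: a standard discretization granularity, coarse enough that bins are
populated at typical panel sizes (tens to a few hundred cell lines per
class), fine enough to see non-linear class dependence. `t` is a reported
parameter, not a tuned one.

The quantization range is computed on the training samples of the current
fold only. Computing it once on the full dataset would leak test-sample
ranges into training; the leakage-guard test asserts the stricter reading.

### Networks and per-node predictors

Pearson correlation with a zero-variance vector is undefined; it is taken
as 0, so constant genes are isolated nodes. Degree-0 nodes predict the
training-class mean of the gene — the zero-covariate regression — which
keeps the MSE rule total for any threshold. Ridge regression is fit in
closed form on centered data with an unpenalized intercept (expression is
not assumed centered) and global `λ = 10⁻³`; with `λ > 0` the normal
equations are always solvable, so training cannot fail on collinear
neighbourhoods. The SVR alternative uses an RBF kernel with a per-node
grid search (`C, γ ∈ {0.1, 1, 10}`, ε-tube fixed at 0.1, inputs not
rescaled), scored by 5-fold cross-validation MSE on the class's training
samples. One seeded fold split is shared by all nodes of a fit — re-splitting
per node would multiply runtime without changing what is estimated — and
grid ties resolve to the smallest `C`, then the smallest `γ` (the least
complex model). If a class has fewer samples than the fold count, the
count is reduced with a warning rather than failing.

Two naming notes: the literature uses `ε` both for the correlation
threshold and for the SVR tube; the code says `corrThreshold` and
`svrEpsilon` throughout. And an exact MSE tie classifies as *resistant* —
an arbitrary but fixed rule, needed so that degenerate models (identical
networks) are deterministic under test.

### Evaluation protocol

`nestedCV()` runs repeated double nested cross-validation: the outer
5-fold loop measures balanced accuracy/MCC, the inner 5-fold loop tunes
the correlation threshold over `{0.4, 0.46, …, 0.94}` by mean balanced
accuracy, and for SVR the per-node grid search adds a third, innermost
loop inside each fit. Both loops are **class-stratified**. Plain random
partitioning can strand a fold without one class at realistic class
imbalances, which makes the metrics undefined; stratification is the
smallest protocol change that keeps 5-fold feasible and is documented here
as a deliberate deviation from fully random splitting. Combinations (for
example, one drug within one cancer type) for which even stratified
splitting would leave an inner validation split without both classes are
reported as `"insufficient"` rather than evaluated (`cvFeasible()`,
`stratifiedSubsetEval()`).

Every quantity is averaged over folds within a repeat, then over repeats;
repeats differ only in the partitioning, all of it derived from
`(seed, repeat, fold)` by a fixed stream-splitting scheme, so identical
seeds give bit-identical reports. The ROC decision score is
`mseResistant − mseSensitive`, the margin of the MSE rule; the classifier
defines no other continuous output. MCC is computed on the 2 × 2 part of a
confusion matrix, dropping ambiguous columns with a warning, and is set to
0 when a marginal factor vanishes. The default repeat count is 10 in the
test protocols; published protocols at 100 repeats are one configuration
key away (`nRepeats`).

## The synthetic generator

`generateDataset()` emulates exactly the structure the classifier assumes
and nothing else. Genes are partitioned into blocks; within a block,
expression is a shared standard-normal latent factor scaled by
`sqrt(withinBlockCorr)` plus independent noise, so with the default
`noiseSd = sqrt(1 − withinBlockCorr)` every gene has zero mean and unit
variance in both classes and within-block correlation equal to the target.
The resistant class reassigns a fraction `blockAssignmentDivergence` of
genes to different blocks by a cyclic interleave — a reassignment that
changes *co-membership*, not just labels, which is what actually alters
the correlation structure. At divergence 0 the classes are exchangeable by
construction. EC50 values are drawn on the score scale around class
centers `ec50Separation` apart, straddling the supplied cutoff pair, so
all three labeling zones are populated.

Defaults were fixed once: 60 genes in 6 blocks, 100 cell lines per class,
within-block correlation 0.9, divergence 1, EC50 separation 2 score units
with SD 0.5. These are the conditions of the package's parameter-recovery
experiments (with `m' = 30` selected features), sized so the full nested
protocol runs in minutes on one core while the per-class sample size (100)
estimates correlations with standard error ≈ 0.1.

What the generator deliberately does **not** model: heteroscedastic
platform noise, batch effects, cancer-type substructure, mean-shift
signal, and — importantly — a *continuum* of correlation strengths. The
generated correlation spectrum is bimodal: within-block pairs near the
target, everything else near zero. Two consequences for interpreting the
tests:

* Passing the recovery test (nested-CV BAC > 0.85 at divergence 1,
  chance-level at divergence 0) shows the pipeline detects
  covariance-borne signal and nothing else; it does not bound performance
  on real transcriptomes, where signal is weaker and partly marginal.
* Across the correlation-threshold grid, every threshold between the
  sampling-noise band (|r| ≲ 0.35 at 100 samples) and the block
  correlation (0.9) yields the *same* edge set, so the accuracy profile is
  flat on the left and only collapses once the threshold exceeds the block
  correlation. The interior-peak shape seen on real data — where too-low
  thresholds admit many weak, harmful edges — requires weak genuine
  correlations that this generator intentionally lacks; the corresponding
  suite check documents this limit rather than papering over it.

## Degenerate inputs and numerical conventions

* Constant expression vectors: term 1 for quantization, correlation 0 for
  network building, class-mean prediction at degree 0.
* `E = 0` cells contribute 0 to χ²; single-class label vectors are an
  error, not a zero.
* Ridge with `λ > 0` never fails; `λ → ∞` predictions converge to the
  training mean (tested).
* Expression values are used exactly as loaded — no normalization or
  z-scoring — because the method is defined on whatever scale the matrix
  arrives in; consequently matrices on different scales should not be
  mixed across training and prediction.
* Missing values are not modelled: rows containing them are dropped at
  load (opt-in via `allowMissing`), duplicated gene rows collapse to the
  first occurrence, both with warnings.
* All library randomness flows through one integer seed via a documented
  arithmetic stream-splitter (`deriveSeed`), and RNG state is restored
  after every internal draw so the package never perturbs user-level
  randomness.

## Known limitations

* Edge construction is marginal correlation, not partial correlation;
  dense blocks create redundant predictors whose errors are correlated
  across nodes, so the per-gene success rates within a block are not
  independent evidence.
* The MSE rule weights all panel genes equally; no attempt is made to
  reweight genes by reconstruction variance.
* SVR models serialize via RDS (`saveNBCModel`); there is no plain-text
  model exchange format because support-vector machines have no faithful
  flat representation.
* Multi-class response levels, signed/directed networks, and the
  publication-evidence analysis that consumes the prediction-success-rate
  profile are out of scope; the profile itself is exported for downstream
  use.
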