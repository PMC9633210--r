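---
title: "Multiomics survival subtyping with survomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiomics survival subtyping with survomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survomics)
```

## The problem

Bulk tumor cohorts are routinely profiled on several omics layers at once
— mRNA expression, miRNA expression, and CpG methylation — together with
follow-up (time to death or censoring). An unsupervised question with
clinical stakes is whether the joint molecular profile partitions
patients into subgroups with different prognosis. survomics implements a
pipeline for this built around a feed-forward autoencoder: integrate the
layers into one feature space, compress them through a bottleneck,
retain the bottleneck features that associate with survival, cluster
patients on those features, and validate the resulting low/high-risk
split internally (fold-based label transfer) and externally
(expression-only cohorts).

The package is organized around one fitting function, `subtype_fit()`,
which returns a classed object with `print`, `summary`, `plot`
(Kaplan-Meier curves) and `predict` (external label transfer) methods.
`method = "pca"` and `method = "snf"` run the two standard alternatives
— principal components in place of the bottleneck, and similarity
network fusion with spectral clustering — through the identical
downstream path, so the three approaches are directly comparable.

## Preprocessing

Count layers are filtered by zero fraction (features with more than 20%
zeros, then samples with more than 20% zeros among the remaining
features). CpG methylation is aggregated to gene promoters — the 1500 bp
immediately upstream of the TSS, strand-aware with inclusive endpoints
(`[TSS-1500, TSS]` on `+`, `[TSS, TSS+1500]` on `-`, 1-based); a gene's
value is the mean beta of its in-window CpGs with missing values
excluded cell-wise. Promoter features and samples are filtered by
missing fraction (same 20% rule, features first), and the remainder is
completed by k-nearest-feature imputation (k = 10, Euclidean distance
over co-observed samples — the convention of the classic microarray
imputation tools). Each layer is then unit-scaled per sample (every
sample row divided by its l2 norm) and the layers are stacked into one
matrix with per-layer provenance.

Two conventions deserve a note:

* *Unit scaling.* Some write-ups print the sample scaling as `v /
  ||v||^2` while calling it "unit scaling". Dividing by the squared norm
  does not produce unit vectors, so the default here divides by the
  norm; the squared variant is available via `unit_scale_samples(norm =
  "l2sq")` for exact emulation of that formula.
* *mad.* Median scale normalization uses `mad(x) = median(|x_i -
  median(x)|)` without the 1.4826 normal-consistency factor, exactly as
  the formula is usually printed in this context.

## The autoencoder

`train_autoencoder()` fits a symmetric multilayer perceptron
(input → 2000 → 500 → 2000 → output by default; the middle layer is the
bottleneck) with tanh activations, a batch-normalization layer after
every hidden dense layer, mean-squared reconstruction error, and Adam
for a fixed 32 epochs — no early stopping and no validation split. It
is implemented directly in R with a small C kernel for the fused Adam
update; on data of the sizes used here that trains in seconds to tens
of seconds and is bit-reproducible given the seed (per device).

Choices the architecture description leaves open, and what this package
does:

* **Batch size 32 and learning rate 1e-3.** Neither is dictated by the
  architecture; 1e-3 is the Adam default of the mainstream deep-learning
  toolkits, and 32 gives stable batch-normalization statistics at the
  cohort sizes involved. Both are `ae_spec()` fields.
* **Batch-norm placement**: each hidden block is dense → tanh → batch
  norm — the normalization layer is appended *after* the hidden layer,
  at every hidden layer (the stated overfitting rationale applies to
  all of them). The bottleneck representation is the middle layer's own
  tanh activation, taken before its appended batch-norm, so the
  representation features keep their natural (unwhitened) scales.
  Inference-mode batch norm uses running statistics (momentum 0.9), so
  encoding is a pure function of the weights and the input.
* **Initialization**: Glorot uniform with an explicit seed.
* **Auto-shrinking**: hidden layers wider than the input are clamped to
  the input width with a warning, which matters for reduced synthetic
  data (e.g. a 512/64/512 network on ~2700 stacked features).

The bottleneck representation is the tanh activation of the middle
layer, so every representation feature lies in (-1, 1).

## Subgroup discovery

Each bottleneck feature is tested in a univariate Cox
proportional-hazards model (Efron ties, Wald p-value); features with p
above 0.10 are screened out ("keep p <= 0.10"). k-means (Lloyd, 20
random restarts, best within-cluster sum of squares, fixed seed) is run
on the retained features for K = 2..6, and K is chosen by the mean
silhouette width, ties broken by the Calinski-Harabasz score and then
by the smaller K. stats::kmeans supplies the clustering; with 20
restarts the additional variance-reduction of k-means++ seeding is not
needed. Finally the clusters are oriented by hazard: a univariate Cox
fit on the cluster indicator names the higher-hazard cluster "high"
(clusters without events fall back to ordering by median observed
time).

## Survival evaluation

`evaluate_survival()` bundles four statistics: the unweighted log-rank
test (chi-square with K-1 df), Harrell's concordance index, an
IPCW Brier score, and per-group Kaplan-Meier curves. Two conventions
are worth spelling out:

* **C-index ties.** `concordance_index()` defaults to the textbook
  definition: over usable pairs (the member with the shorter observed
  time had the event), count score ties 1/2. For a *binary* group label
  and roughly balanced groups, nearly half of all usable pairs are
  within-group score ties, which pins that version of the index near
  0.63 no matter how well the groups separate. Published C-indexes for
  two-group prognostic labels are consistent with the other convention
  — dropping score-tied pairs, so the index becomes the cross-group
  concordance probability (≈ HR/(1+HR) for exponential hazards).
  `evaluate_survival()` therefore uses `ties = "exclude"` for group
  labels; both modes are exposed.
* **Brier horizon.** The single-number Brier score is evaluated at the
  median observed follow-up by default, with the prediction for each
  sample being its group's Kaplan-Meier survival at that horizon, and
  censoring weights from the Kaplan-Meier estimate of the censoring
  distribution (1/G(T-) for events before the horizon, 1/G(t) for
  subjects still at risk, 0 otherwise). An integrated version
  (`integrated_brier_score()`) is provided as well.

`cox_fit()` wraps the survival package's partial-likelihood fit and
reports hazard ratios, 95% Wald intervals, z and p per covariate plus
the model-level score test — the shape of a standard risk-factor table.

## Internal and external validation

`make_cv_plan()` splits samples into 5 random near-equal folds and
enumerates all 10 combinations of 2 test folds versus 3 training folds,
so every sample is tested exactly 4 times. Per combination,
`cross_validate()` retrains the autoencoder on the training samples
only (seed = base seed + combination index), rediscovers training
subgroups — Cox screening then k-means at the *discovery* cluster
number (the validation verifies the fitted subgroup structure, so it
inherits K = 2 rather than re-running the K scan; `k = NULL` re-selects
if wanted) — selects the top 50 mRNA / 30 miRNA / 50 methylation
features by one-way ANOVA against those labels, scales each omics block with its
own recipe (mRNA and methylation: median scale then robust scale;
miRNA: median scale then per-feature unit scaling), fits an RBF-kernel
SVM with a 5-fold grid search over cost and gamma (the SVM
standardizes features internally, its stock behavior, which keeps the
gamma grid on the scale it was designed for), predicts the test
samples, and evaluates the survival separation of the predicted
groups. A transfer that collapses to a single class is scored as
finding no separation (log-rank p of 1, chance-level concordance)
rather than being dropped. The summary reports the geometric mean of log-rank p-values and
mean ± sd of C-index and Brier score, per omics set.

Scaling parameters are fit independently per set (training, test,
external) rather than frozen on the training set: medians and scale
factors differ systematically across platforms, and the normalization
is applied "wherever the classifier is used". The alternative
(train-fit, test-apply) is a one-line change around
`scale_for_classifier()` if a user needs it. ANOVA selection operates
on the scaled values.

`transfer_labels()` (also available as `predict()` on the fitted
object) carries the discovered subgroups to an expression-only external
cohort: intersect genes, ANOVA-select the top 50 on the full discovery
cohort, scale each cohort independently, fit the SVM on discovery,
predict external labels, and — when external follow-up is supplied —
evaluate the transferred separation.

## Baselines

The PCA baseline replaces the bottleneck with centered principal
component scores (component count = bottleneck width, clamped to the
rank bound with a warning) and runs the identical screening/clustering
path. The SNF baseline builds one affinity matrix per omics layer
(distance = 1 - Pearson correlation between sample profiles; locally
scaled Gaussian kernel with K = 14 neighbours and sigma = 0.3), fuses
them by T = 27 rounds of cross-diffusion of full kernels through
K-nearest-neighbour kernels (with the stabilizing identity trick of the
original algorithm), and clusters the fused network by
normalized-Laplacian spectral clustering, choosing K by the largest
eigengap over 2..6 when not given. Pearson correlation is the default
(a Spearman flag exists); exchangeability of the view order and
symmetry of the fused matrix are pinned by tests.

## Differential analysis

Between the discovered subgroups, counts are normalized by
median-of-ratios size factors (log-scale median, the reference
semantics), log2(x+1)-transformed and tested per gene with a Welch
t-test; log2 fold change is the difference of group means on that
scale; significance requires |log2FC| > 1 and BH FDR < 0.05. This is a
deliberately transparent approximation of a negative-binomial GLM
pipeline: the thresholds are the method's own rules, but gene lists
will differ from a full NB analysis, and the documentation says so.
Methylation betas are clipped to [1e-6, 1-1e-6] and mapped to M values
(log2(b/(1-b))); the two-group comparison uses a moderated t-test with
closed-form empirical-Bayes variance shrinkage — prior df and prior
variance estimated by moment-matching the log residual variances
against the scaled-F model, posterior variances
(d0·s0² + d·s²)/(d0 + d), and d0 + d degrees of freedom. Forcing the
prior df to 0 reproduces ordinary t statistics exactly; infinity pools
all features to the prior variance. Significance requires |M
difference| > 1 and FDR < 0.05. BH adjustment is stats::p.adjust.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage is testable with known
ground truth. Its defaults are the study conditions of a
stomach-adenocarcinoma discovery cohort: 363 patients, two latent risk
groups of near-equal size, ~60% right censoring (219/363), median
overall survival near 463 days, a between-group hazard ratio of about
2.4, and paper-scale feature counts. The generative model:

* **Counts** (mRNA, miRNA): negative binomial with log-normal gene
  means (meanlog 4, sdlog 2) and the standard decreasing
  mean-dispersion trend alpha(mu) = 0.05 + 2/mu. The trend matters: with
  a large constant dispersion, the handful of top-expressed genes
  dominate every sample's l2 norm with large multiplicative noise, and
  after raw-count unit scaling *no* method — autoencoder, PCA or SNF —
  can recover even a strong latent group shift. Real RNA-seq does not
  behave that way: highly expressed genes are proportionally much less
  dispersed, which is exactly what the trend encodes.
* **Signal**: a `signal_fraction` of features per layer shifts between
  groups by ±`effect_size` on the latent scale (log mean for counts,
  logit for methylation). Methylation signal is placed in promoter
  CpGs of signal genes so that promoter aggregation carries it through.
* **Methylation**: logit-normal betas; CpGs are laid out on a synthetic
  five-chromosome genome with genes on both strands (promoter
  aggregation is strand-exercised), ~80% of CpGs in promoter windows,
  plus a small missing-at-random mask so imputation runs.
* **Survival**: exponential event times with hazard ratio
  exp(`true_log_hr`) per group step; independent exponential censoring
  whose rate is solved numerically so the expected censored fraction
  hits `censor_rate`; `censor_rate = 0` disables censoring entirely.
* **Clinical covariates** (age, gender, stage) are independent of the
  group unless the `confounding` knob is raised.

`simulate_external_cohort()` draws new patients from the same
group-to-hazard mechanism, observed only through mRNA intensities on
the log scale with Gaussian noise and an additive `platform_shift` —
an idealized microarray cohort.

What the generator does *not* emulate: batch effects beyond the single
platform shift, copy-number or proteomic layers, gene-gene correlation
beyond the group structure, or non-proportional hazards. Passing tests
on these cohorts therefore demonstrates that the pipeline's machinery
is correct and recovers planted structure under the stated conditions —
not that it will find clinically meaningful subgroups in any particular
real dataset.

## Problem sizes used by the test-suite and acceptance script

The package's own checks run at reduced scale so they complete quickly
on a single CPU: the headline discovery checks use n = 200 patients
with 2000 mRNA + 300 miRNA + 2000 CpG features and a 512/64/512
network across 10 seeds; internal validation runs the full 10-fold
CV-like plan on that cohort; null-calibration checks use n = 100-150
with a 32/8/32 or 64/16/64 network over 100 replicates; Cox
hazard-ratio recovery uses 200 replicates of n = 1000. These sizes are
the package's chosen test conditions, stated here so results are
interpreted at the right scale.

## Numerical and degenerate-input behavior

* Zero-norm samples are left at zero (with a warning) by unit scaling;
  features with mad 0 or trimmed sd 0 are divided by 1 and flagged.
* Trimmed sets with fewer than 2 values fall back to the full mean/sd.
* Constant features are dropped from Cox screening with a warning;
  screening that removes everything raises an error suggesting a larger
  alpha rather than silently continuing.
* k-means restarts on degenerate (duplicated-row) inputs can produce
  empty clusters; the best-WCSS restart is used and the warnings are
  suppressed as benign.
* Betas are clipped before the M transform, never dropped.
* In null-calibration settings, replicates in which no bottleneck
  feature passes screening are counted as "no subgroups discovered"
  (log-rank p of 1), which is the conservative reading.

## Known limitations

* The autoencoder is trained for a fixed 32 epochs; on small cohorts
  the quality of the bottleneck representation varies with the
  initialization seed, and occasionally the clustering latches onto a
  non-prognostic direction. The CV-like internal validation exists
  precisely to expose that instability.
* The count-layer differential analysis is a transparent approximation,
  not a negative-binomial GLM; gene lists will differ from DESeq2-class
  tools in the tails.
* Determinism is per device: BLAS differences across platforms can
  change trained weights in the last bits.
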