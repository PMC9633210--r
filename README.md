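# survomics

Unsupervised discovery of prognosis-related patient subgroups from bulk
multiomics data (mRNA counts, miRNA counts, CpG methylation), with
survival evaluation, fold-based internal validation, external-cohort
label transfer, and PCA / similarity-network-fusion baselines.

## Who this is for

Computational biologists who have, for one cohort, three
samples-by-features matrices plus follow-up (time, event), and want to
ask: *does the joint molecular profile split these patients into groups
with different survival?* — and then stress-test the answer.

## The method

1. **Preprocess.** Filter count features/samples by zero fraction
   (> 20% excluded, features first), average CpG betas over gene
   promoters (the 1500 bp upstream of the TSS, strand-aware), filter by
   missing fraction, impute the rest by k-nearest features, unit-scale
   each sample row, `v_normed = v / ||v||_2`, and stack the layers.
2. **Integrate.** Train a feed-forward autoencoder (default hidden
   layers 2000-500-2000, tanh, batch normalization after each hidden
   layer, mean-squared reconstruction error, Adam, 32 epochs). The
   middle layer is the bottleneck representation.
3. **Discover.** Fit a univariate Cox proportional-hazards model per
   bottleneck feature and keep those with Wald p ≤ 0.10; k-means the
   kept features (20 restarts), choosing K in 2..6 by silhouette index
   with Calinski-Harabasz tie-breaks; name the higher-hazard cluster
   the high-risk group.
4. **Evaluate.** Log-rank test, Harrell's C-index (tie-excluded
   convention for group labels), IPCW Brier score at the median
   follow-up, Kaplan-Meier curves; univariate/multivariate Cox tables
   via `cox_fit()`.
5. **Validate.** 5 folds, all 10 (3 train, 2 test) combinations: per
   combination retrain the autoencoder, rediscover training subgroups,
   select the top 50/30/50 features per omics by ANOVA, scale per the
   per-omics recipes (median+robust for mRNA/methylation, median+unit
   for miRNA), fit an RBF-SVM with a 5-fold grid search and predict the
   held-out samples. Externally, transfer labels to an expression-only
   cohort through the shared genes.
6. **Compare.** The same downstream path with PCA scores in place of
   the bottleneck, and SNF (K = 14, sigma = 0.3, T = 27; correlation
   distance; spectral clustering with eigengap K) as a second
   alternative.

A synthetic-cohort generator (`simulate_cohort()`) with known subgroup
labels, negative-binomial counts (trended dispersion), logit-normal
methylation on a strand-aware synthetic genome, group-dependent
exponential survival and tuned censoring makes every stage testable
without external data.

## Worked example

```r
library(survomics)

cfg <- sim_config(n_samples = 200, n_mrna = 2000, n_mirna = 300,
                  n_cpg = 2000, n_genes_annotated = 500,
                  signal_fraction = 0.05, effect_size = 1,
                  true_log_hr = log(3), seed = 1)
cohort <- simulate_cohort(cfg)
fit <- subtype_fit(cohort, ae = ae_spec(c(512, 64, 512), seed = 1), seed = 1)
fit
#> multiomics subtype fit (autoencoder): 200 samples, K = 2
#>
#>  low high
#>  100  100
#> log-rank p = 5.85e-07, C-index = 0.753, Brier = 0.181
```

The fit chose K = 2 (silhouette scan over 2..6), and the discovered
low/high-risk split separates survival strongly: a log-rank p of
5.9e-07 against the planted hazard ratio of 3, a tie-excluded C-index
of 0.75 (the cross-group concordance probability; HR/(1+HR) ≈ 0.75 is
its theoretical value here), and an IPCW Brier score of 0.18 at the
median follow-up. Against the known simulation labels this run recovers
the truth exactly (adjusted Rand index 1.0). `summary(fit)` prints the
cluster-number scan and screening counts, `plot(fit)` draws the KM
curves, and

```r
ext <- simulate_external_cohort(cfg, cohort, n_samples = 200)
tr  <- predict(fit, ext$expression, surv = ext$survival)
tr$evaluation$logrank_p
```

transfers the subgroups to a platform-shifted external cohort through
an ANOVA-selected 50-gene SVM and evaluates them there.

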