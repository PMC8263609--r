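# proxsurv

Risk stratification for right-censored oncology cohorts with
high-dimensional radiomic-style features.

Radiomic panels routinely contain hundreds of correlated intensity, shape
and texture features — far too many for a moderate cohort with a ~20%
event rate. `proxsurv` collapses the whole feature space into a single
categorical covariate, a **patient cluster label**, by an
outcome-supervised route:

1. filter the features (zero variance, pairwise |r| > 0.99, |r| > 0.80 to
   the tumor-volume / mean-intensity anchors), statistics from training
   rows only;
2. grow a random survival forest (1000 trees, log-rank splitting, minimum
   node size 5) on the filtered training features;
3. compute the **in-bag proximity** of every patient pair — the fraction
   of trees, among those where both are in the bootstrap sample, in which
   they share a terminal node — and convert it to a dissimilarity
   `D = 1 - P`;
4. cluster patients by **Ward agglomeration** on `D` (Lance–Williams
   recurrence; the merge criterion is
   `δ(c₁,c₂) = |c₁||c₂|/(|c₁|+|c₂|) · ‖c̄₁ − c̄₂‖²`) and cut at k ∈ 2–4;
5. label held-out patients with a **multinomial log-linear model** over
   the forest's most frequently split features;
6. feed the label to a **stacked ensemble** — Cox PH, random survival
   forest, and IPCW-weighted random forest / logistic regression /
   logistic elastic net — combined by **non-negative least squares** on
   5-fold out-of-fold predictions of the 5-year event probability;
7. evaluate with Harrell's C-index, IPCW-weighted 5-year AUC, per-cluster
   Kaplan–Meier curves and the log-rank test.

Censoring is handled throughout by inverse-probability-of-censoring
weights at the 60-month horizon: patients with an observed event get
weight `1/Ĝ(T⁻)`, horizon survivors `1/Ĝ(60)`, and patients censored
event-free before the horizon weight exactly 0, where `Ĝ` is the
Kaplan–Meier estimate of the censoring distribution.

A seeded synthetic-cohort generator reproduces the statistical shape of
the target application (500 patients, 300 features in correlated blocks,
two latent risk phenotypes at hazard ratio 3, ~20% events, 80/20 split),
so the whole pipeline is testable without any data download.

## Worked example

```r
library(proxsurv)

cfg <- pipeline_config(seed = 1)      # default synthetic cohort
report <- run_pipeline(cfg, verbose = FALSE)
report
```

```
<pipeline_report> 400 train / 100 test; clusters 247/153
  log-rank: train p = 1.83e-21, test p = 0.722
  clinical               C-index 0.500/0.500  AUC 0.500/0.500 (train/test)
  clinical+clusters      C-index 0.877/0.553  AUC 0.982/0.558 (train/test)
```

Reading the output: the 400 training patients split into clusters of 247
and 153 whose Kaplan–Meier curves separate very strongly on the training
split (the clustering is outcome-supervised, so strong in-sample
separation is expected) and — with only ~20 events among 100 test
patients — not significantly on the held-out split. The clinical
covariates are generated independently of the risk phenotype, so the
clinical-only ensemble collapses to a constant predictor (AUC exactly
0.50); adding the single cluster covariate raises held-out
discrimination (AUC 0.56, C-index 0.55). Against the generator's truth,
the training clusters recover the latent phenotype with an adjusted Rand
index of 0.82:

```r
co <- generate_cohort(cohort_config(seed = proxsurv:::stage_seed(1, 1)))
latent <- cohort_data(co, "train", include_latent = TRUE)$latent_group
adjusted_rand_index(report$train_labels, latent)
#> [1] 0.8184069
```

Lower-level entry points (`fit_survival_forest()`, `inbag_proximity()`,
`ward_agglomerate()`, `cut_dendrogram()`, `fit_assignment_model()`,
`ipcw_weights()`, `fit_stacked_ensemble()`, `harrell_c_index()`,
`auc_horizon()`, `logrank_test()`) expose each stage separately; the
`exec/proxsurv` script wraps simulation and the full pipeline for shell
use. See the vignette in `vignettes/proximity-clustering.Rmd` for the
model, its assumptions and the design choices.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "proxsurv", load_package = "installed")'
```

Unit tests cover every module against independent oracles (brute-force
proximity enumeration, greedy Ward recomputation from coordinates,
product-limit hand values and `survival::survfit`, O(n²) concordance
enumeration, closed-form IPCW calibration, exact NNLS mixture recovery).

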