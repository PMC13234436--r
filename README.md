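# nacstrat

Machine-learning stratification of neoadjuvant-chemotherapy (NAC) response
in muscle-invasive bladder cancer (MIBC), as a tested, reusable R package.

Only ~half of MIBC patients respond to cisplatin-based NAC; the rest incur
toxicity and surgical delay for nothing. `nacstrat` implements the two-arm
workflow used to build pre-treatment response predictors:

- **Transcriptome arm** — nine per-gene expression scalers (log2,
  log2_minmax, standard, minmax, max_abs, robust, Yeo–Johnson power,
  quantile, RankGauss) with a Gaussianity gate and random-forest
  premodeling; data-driven gene-classifier extraction from ensembles of
  10 random forests × 100 trees; classifier reduction by mutual
  information, variance-inflation factor and hierarchical clustering
  (accepted when ΔAUC < 0.2); top-10 and union classifier variants; and the
  fully enumerated multicohort cross-validation design — with 4 cohorts and
  17 classifiers, 2 × 17 × 3 × 12 = 1,224 runs scored by accuracy, recall,
  precision, F1, MCC (Matthews correlation) and mid-rank Mann–Whitney AUC.
- **Digital-pathology arm** — recursive feature elimination with 3-fold
  cross-validation (RFECV) over tumor/stroma protein intensities; ten
  5 + 5 marker gene pools; forward/backward stepwise search for 2–5 marker
  panels under mean 3-fold balanced accuracy with depth-3 decision trees or
  logistic regression; and Kaplan–Meier / log-rank comparison of overall
  and progression-free survival between predicted response groups.

A synthetic-data module generates multicohort expression matrices and
two-compartment pathology tables with known planted ground truth (effect
sizes, predictive markers, proportional-hazards survival coupling), so the
entire pipeline is testable offline; the real study cohorts are not
required. See `vignettes/nac-response-stratification.Rmd` for the full
methods account.

## Worked example

```r
library(nacstrat)

## transcriptome arm: a 16-patient discovery cohort with 5 planted genes
sim <- generate_cohorts(cohort_sim_spec(cohort_sizes = c(16, 23),
                                        n_genes = 200, n_informative = 5,
                                        seed = 42))
amc <- sim$cohorts[[1]]
amc
#> <expression_cohort 'cohort1'> 200 genes x 16 samples (NR = 8, R = 8)

ens <- rf_ensemble_scores(amc, seed = 42)          # 10 forests x 100 trees
cl  <- extract_data_driven_classifier(ens, amc, name = "AMC_data_driven")
cl
#> <gene_classifier 'AMC_data_driven'> 5 genes (data-driven)
#>   G0002, G0049, G0159, G0108, G0193

red <- reduce_classifier(amc, cl, target_max = 6)  # MI -> VIF -> clustering
red$report
#> <reduction_report> 5 -> 5 genes (MI dropped 0, VIF 0, cluster 0)
#> AUC full 1.000, reduced 1.000, delta 0.000
delta_auc_check(red$report)
#> [1] TRUE

enumerate_runs(paste0("cohort", 1:4), sprintf("cl%02d", 1:17))
#> <run_matrix> 1224 runs (17 classifiers x 2 variants x 3 models x 12 role pairs)
```

With 16 patients and 200 genes the extracted 5-gene classifier keeps only
one planted gene (G0002) — small discovery cohorts genuinely behave this
way, and the in-cohort AUC of 1.0 shows why out-of-cohort validation is the
arm's whole point. The run matrix reproduces the design arithmetic exactly:
12 (train, validation, test, test) role rotations of four cohorts.

```r
## pathology arm: 55 NAC + 36 PCT patients, 2 predictive markers among 12
path  <- generate_pathology(pathology_sim_spec(n_patients = c(55, 36),
                                               n_markers = 12,
                                               n_predictive = 2, seed = 42))
pools <- build_pools(path$table, n_pools = 3, seed = 42)
fit   <- search_best_panel(path$table, pools, sizes = 2:4, bases = "tree",
                           data_types = "standardized", seed = 42)
fit
#> Marker-panel model for NAC response prediction
#> <marker_panel> 2 markers (tree, standardized data, forward selection)
#>   M001__stroma, M002__stroma
#> threefold CV balanced accuracy: 0.892 (search over 18 configurations)

stratify_predicted(fit, path$table)
#> <stratification> predicted groups: response = 43, nonresponse = 48
#>   NAC.os         log-rank p = 0.04144
#>   NAC.pfs        log-rank p = 0.005459
#>   PCT.os         log-rank p = 0.03704
#>   PCT.pfs        log-rank p = 0.1634
#>   combined.os    log-rank p = 0.003184
#>   combined.pfs   log-rank p = 0.001234
```

The search recovered exactly the two planted markers (M001, M002; the
stroma copy of the planted signal), and the predicted groups separate
survival: nonresponders were simulated with a 2.5-fold hazard, and the
log-rank test on the *predicted* groups finds that difference (combined
OS p ≈ 0.003) — the end-to-end property the acceptance suite measures over
many seeds.

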