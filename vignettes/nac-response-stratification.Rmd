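---
title: "Methods: multicohort NAC-response stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multicohort NAC-response stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nacstrat)
```

## The problem

Roughly half of muscle-invasive bladder cancer (MIBC) patients gain no
benefit from cisplatin-based neoadjuvant chemotherapy (NAC) yet still incur
its toxicity and the delay to surgery. `nacstrat` implements a two-arm
machine-learning workflow for stratifying patients into predicted responders
(R) and nonresponders (NR) before treatment:

1. a **transcriptome arm** — multicohort expression scaling and
   harmonization, data-driven gene-classifier extraction from random-forest
   importance ensembles, classifier reduction, and an exhaustively
   enumerated cross-cohort validation design; and
2. a **digital-pathology arm** — recursive feature elimination with
   cross-validation (RFECV) over tumor- and stroma-compartment protein
   intensities, stepwise optimization of a 2–5 marker
   immunohistochemistry panel, and Kaplan–Meier / log-rank comparison of
   survival between predicted response groups.

Patient-level data are replaced by a synthetic-data module with known ground
truth, so every stage is testable offline and the recovery of planted
signal can be measured exactly.

## Synthetic data: what it emulates and what it does not

`cohort_sim_spec()` / `generate_cohorts()` emulate the study design the
package targets: four transcriptome cohorts of 16 (8 NR / 8 R), 23, 38 and
299 patients sharing a gene namespace but differing in location, scale and
marginal shape (Gaussian or lognormal), with a small planted set of
response-informative genes carrying a standardized mean shift *d* between
classes. Class effects are applied **before** cohort distortion, so
distortion never destroys within-cohort separation on standardized data — a
property the tests assert. Noise is independent Gaussian per gene; the
lognormal shape is obtained by exponentiating the Gaussian core, which
preserves rank structure while exercising the skew-removing scalers.

Default generator conditions (chosen once, as study conditions, not tuning
dials): `effect_size = 2` for informative genes — a strong but realistic
single-gene effect corresponding to a per-gene AUC of
`pnorm(2 / sqrt(2)) ≈ 0.92`; `n_genes = 500` and `n_informative = 10` at
desk scale; per-cohort shifts `(0, 1, −1, 2)` and scales `(1, 2, 0.5, 1.5)`
that are large relative to the class effect, so naive pooling fails without
scaling; label noise 0 by default so model error can be separated from
label error.

`pathology_sim_spec()` / `generate_pathology()` emulate the
immunohistochemistry tables: 55 NAC + 36 PCT patients, 74 protein markers
quantified in tumor and stroma compartments, three replicate TMA cores per
patient whose mean is the per-patient value, and response rates of 21/55
(NAC) and 25/36 (PCT). Intensities are lognormal; predictive markers are
shifted on the log scale by `effect_size` standard deviations of the
per-patient mean. Survival is exponential with the nonresponders' hazard
multiplied by `hazard_ratio` (default 2.5) and independent exponential
censoring calibrated to `censor_rate`; the exponential baseline was chosen
because it admits closed-form calibration checks (the log-rank type-I error
simulation in the tests).

What the simulator does **not** model: gene–gene correlation beyond planted
effects, batch structure within a cohort, platform-specific detection
limits, molecular-subtype biology (subtypes would enter only as a label
column), informative censoring, or image-level IHC artifacts. Passing tests
therefore demonstrate that the machinery recovers signal under idealized
noise, not that the pipeline's clinical conclusions transfer to real data.

## Scaling and the Gaussianity gate

Nine per-gene scalers are provided (`apply_scaler()`): `log2` (pseudocount
1, since raw pseudocount choice is otherwise arbitrary), `log2_minmax`,
`standard`, `minmax`, `max_abs`, `robust`, `power` (Yeo–Johnson),
`quantile` (rank interpolation onto a fixed 100-point grid mapped through
the standard-normal quantile function) and `rankgauss`
(`qnorm((rank − 0.5)/n)` with mid-ranks). The Yeo–Johnson λ is fitted per
gene by maximizing the closed-form profile log-likelihood with a
one-dimensional search on [−5, 5], then the transformed gene is z-scored;
the fit is cross-checked against `car::powerTransform` in the tests.
Constant genes map to 0 (`standard`, `robust`) or 0.5 (`minmax`) with a
warning, avoiding NaN propagation. Scalers are fitted per cohort by
default, because the point of this stage is the removal of cohort-specific
location/scale differences.

`gaussianity_gate()` retains the scalers whose output looks Gaussian:
mean per-gene |skewness| ≤ 0.5 and mean per-gene |excess kurtosis| ≤ 1.0.
These thresholds were set so that on lognormal-like input the gate passes
the standard, power and rank-based transforms while rejecting range
scalers — the three-method gate the downstream premodeling expects. The
gate is a heuristic screen, not a formal normality test; with vacuous
thresholds it passes everything.

`premodel_select_scaler()` then fits a random forest per
(cohort, classifier) combination for each gated method, evaluates accuracy,
recall, precision, F1 and MCC from the out-of-bag votes, and selects the
method with the highest mean MCC (ties: higher mean F1, then fixed method
order). MCC was chosen as the deciding metric because it is the only one of
the five that is balanced under class asymmetry; the tie-break chain makes
the selection deterministic.

## Data-driven classifiers

`rf_ensemble_scores()` fits 10 random forests of 100 trees (forest *f*
seeded `seed + f`), a design aimed at very small discovery cohorts (n = 16)
where a single forest's importance ranking is unstable. Prediction scores
are the mean **out-of-bag** vote fraction for class R — out-of-model
scoring was chosen deliberately: in-sample scores on 16 patients are
trivially perfect and carry no information. Genes are canonicalized to
lexicographic order before fitting so results do not depend on storage
order.

`extract_data_driven_classifier()` sweeps the top-k importance sets for
k in [5, 30], hierarchically clusters samples (Ward, Euclidean) on each
standardized k-gene submatrix, cuts at two clusters and scores agreement
with the NR/R labels by the adjusted Rand index; the smallest k attaining
the maximum wins. The original procedure selected k from heat maps by eye;
the ARI of a 2-cut dendrogram is this package's deterministic surrogate for
that visual judgement and is a design decision, not a reproduction.

`reduce_classifier()` applies three sequential filters on power-scaled
expression: mutual information with the labels (plug-in estimate on 4
quantile bins; threshold 0.01 nats — the data-processing chain gives no
published threshold, so a small positive floor is used), iterative removal
of the maximum-VIF gene while max VIF > 10 (the conventional collinearity
bound; VIF by OLS of each gene on the rest, with p ≥ n collinearity treated
as infinite VIF), then hierarchical clustering of the survivors with one
highest-MI representative per cluster down to `target_max`. If everything
is filtered, the single highest-MI gene is kept with a warning. The report
carries every dropped gene and the ΔAUC of in-cohort logistic scores
(full vs reduced); `delta_auc_check()` passes reductions with |ΔAUC| < 0.2.

Logistic fits fall back to a ridge-stabilized IRLS (penalty 1e-6) when the
data are completely separated — detected both from `glm` warnings and
structurally from non-overlapping linear predictors — because the maximum
likelihood estimate does not exist under separation and tiny cohorts
separate often.

## The cross-validation design

`enumerate_runs()` materializes the full design: every ordered
(train, validation) pair of distinct cohorts, the remaining cohorts being
test sets, crossed with classifiers × variants (top10 / union) × models
(logistic / tree / forest). Four cohorts give 12 role assignments and, with
17 classifiers, 1,224 runs — the design arithmetic the acceptance script
recomputes. `harmonize()` first restricts to genes present in all cohorts
whose scaled distributions agree pairwise (Welch t-test, p > 0.05 in every
pair; α = 0.05 is this package's choice, as is the pairwise form — the
source method states neither). `compute_metrics()` implements all six
metrics in closed form with the 0/0 → 0 convention and a mid-rank
Mann–Whitney AUC, each verified against brute-force oracles.

Decision-tree defaults (Gini, max depth 3, min leaf 2) mirror the
pathology arm's depth-3 trees; forests inside runs use 100 trees seeded
from the run seed.

## Marker-panel optimization

`rfecv_rank()` uses standard RFE semantics: the feature whose removal
degrades mean stratified 3-fold balanced accuracy least is eliminated each
round, and rank 1 is the last survivor. The source description ("a feature
whose removal improved performance was assigned a higher rank") reads as
inverted relative to standard RFE; standard semantics were adopted and the
discrepancy is documented here. `build_pools()` reruns the ranking with
reseeded fold assignments to build ten content-distinct pools of five tumor
plus five stroma markers — pool construction beyond the counts is
unspecified in the source, and reseeded folds were chosen because they
yield exactly the required shape while probing selection stability.

`forward_select()` / `backward_eliminate()` run greedy stepwise search to
the requested size (2–5), followed by a floating refinement that
hill-climbs on single-marker swaps until no swap improves the criterion —
the "forward–backward" character of the original stepwise procedure, and a
standard remedy for greedy suboptimality (the tests compare both directions
against exhaustive best subsets on 8-feature pools, requiring agreement
within 0.02). The criterion throughout is mean 3-fold **balanced**
accuracy, because the NAC and PCT cohorts have opposite class balances
(21/34 vs 25/11) and plain accuracy would reward majority voting. Ties are
broken toward fewer markers, then lexicographically.

`search_best_panel()` — the package's central fitting function — iterates
pools × sizes × bases × directions × data types ("raw" and per-marker
z-scored "standardized" views), replaces the incumbent only on strictly
higher balanced accuracy (the unstated "predefined performance criteria" of
the original), logs every configuration, refits the winning panel on all
patients and returns a classed `nac_panel` object with `print`, `summary`,
`predict` and `plot` methods.

## Clinical-style evaluation

`heuristic_cutoff()` operationalizes "heuristic" marker dichotomization as
the maximally selected chi-square over all midpoints between adjacent
observed values — deterministic and common in clinical practice, but
**anti-conservative**: under the null the test at the selected cutoff
rejects far above its nominal level (a property the tests demonstrate with
a simulation rather than correct, since the original applies no
correction either). `univariate_or()` uses the Haldane–Anscombe 0.5
correction on zero cells and Wald intervals on the log scale, matching
typical clinical-software output. `backward_stepwise_logistic()` removes
the largest Wald p until all remaining p < α; with α = 1 it is the identity
on the predictor set.

`ratio_analysis()` computes marker/denominator ratios **per core** and then
averages over the three replicate cores (ratio-then-mean); mean-then-ratio
was rejected as inconsistent with per-core ratio computation, and cores
with non-positive denominators are skipped with a warning. Group means are
compared by Welch's t-test and z-scored across markers.

Kaplan–Meier curves and log-rank tests are computed through the `survival`
package (`survfit` / `survdiff`; events precede censorings at tied times),
with hand-computed product-limit and O/E/V tabulations kept as independent
oracles in the tests. `stratify_predicted()` assigns every patient to a
predicted response group via the fitted panel and compares OS and PFS per
cohort and combined. Cox modeling is deliberately out of scope, as is
multiple-testing correction across the univariate marker screen (a known
limitation of the original design, documented rather than repaired).

## Numerical choices and problem sizes

All randomized stages take explicit integer seeds and restore the caller's
RNG state; identical inputs and seeds give bit-identical outputs. Fixture
TSVs are written with 17 significant digits so doubles round-trip exactly.
Tie-breaks are fixed everywhere (score, then lexicographic identifier) so
reruns and platform changes cannot reorder results.

The test and acceptance simulations run at desk scale by the package's own
choice: recovery suites use 20 seeds, cohorts of 40–200 samples with
100–500 genes, pathology tables of 8–74 markers, 2 pools with sizes 2–3 for
the end-to-end search, and 500 replicates for the log-rank type-I
calibration. These sizes keep every property measurable with tight Monte
Carlo error while remaining small enough to re-run routinely; the
full-scale defaults (four cohorts, 74 markers, ten pools, sizes 2–5) remain
the documented defaults of the generator and search functions.

## Known limitations

- The synthetic benchmark cannot reproduce the original patient-level
  results (per-classifier AUC rankings, odds-ratio tables, survival
  p-values); those depend on deposited cohort data outside this package's
  scope. The acceptance layer therefore checks design arithmetic exactly
  and method properties statistically.
- RFECV with redundant predictive markers can eliminate one of a correlated
  pair early (its removal costs little while the partner remains); pool
  reseeding mitigates but does not remove this.
- The ARI dendrogram surrogate for heat-map classifier selection and the
  balanced-accuracy replacement rule are this package's operationalizations
  of visually or vaguely specified steps; alternatives (silhouette scores,
  F1-based replacement) would be defensible.
- The heuristic cutoff's selection bias is documented, not corrected.
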