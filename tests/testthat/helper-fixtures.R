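# Shared fixture builders: small planted cohorts and pathology tables.

tiny_cohort <- function(n = 40L, n_genes = 60L, n_informative = 5L,
                        effect_size = 2, seed = 1L, shape = "gaussian") {
  generate_cohorts(cohort_sim_spec(
    cohort_sizes = n, class_balance = 0.5, n_genes = n_genes,
    n_informative = n_informative, effect_size = effect_size,
    cohort_shift = 0, cohort_scale = 1, shape = shape, seed = seed))
}

tiny_pathology <- function(n_patients = c(30L, 25L), n_markers = 8L,
                           n_predictive = 2L, effect_size = 2,
                           hazard_ratio = 2.5, censor_rate = 0,
                           cores = 3L, seed = 1L) {
  generate_pathology(pathology_sim_spec(
    n_patients = n_patients, n_markers = n_markers,
    n_predictive = n_predictive, cores_per_patient = cores,
    effect_size = effect_size, hazard_ratio = hazard_ratio,
    censor_rate = censor_rate, seed = seed))
}

# Brute-force AUC oracle: fraction of concordant positive-negative score
# pairs, ties counted half.
auc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
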