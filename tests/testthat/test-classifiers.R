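test_that("ensemble scores are deterministic, bounded and record the config", {
  sim <- tiny_cohort(n = 16, n_genes = 40, seed = 1)
  ens1 <- rf_ensemble_scores(sim$cohorts[[1]], seed = 7)
  ens2 <- rf_ensemble_scores(sim$cohorts[[1]], seed = 7)
  expect_identical(ens1$mean_scores, ens2$mean_scores)
  expect_identical(ens1$mean_importance, ens2$mean_importance)
  expect_equal(ens1$n_forests, 10L)
  expect_equal(ens1$n_trees, 100L)
  expect_true(all(ens1$mean_scores >= 0 & ens1$mean_scores <= 1))
  expect_true(all(ens1$mean_importance >= 0))
  expect_gt(sum(ens1$mean_importance), 0)
  single <- sim$cohorts[[1]]
  single$labels[] <- 1L
  expect_error(rf_ensemble_scores(single), "per class")
})

test_that("ensemble importance is invariant to gene ordering", {
  sim <- tiny_cohort(n = 20, n_genes = 30, seed = 2)
  co <- sim$cohorts[[1]]
  perm <- rev(seq_len(nrow(co$values)))
  co_perm <- expression_cohort(co$values[perm, ], co$labels, co$cohort_id)
  imp <- rf_ensemble_scores(co, seed = 3)$mean_importance
  imp_perm <- rf_ensemble_scores(co_perm, seed = 3)$mean_importance
  expect_equal(imp[sort(names(imp))], imp_perm[sort(names(imp_perm))],
               tolerance = 1e-12)
})

test_that("a perfectly separating gene dominates the importance ranking", {
  hits <- vapply(1:20, function(s) {
    set.seed(s + 100)
    n <- 30
    labels <- rep(c(0L, 1L), each = n / 2)
    v <- matrix(rnorm(20 * n), nrow = 20,
                dimnames = list(sprintf("G%04d", 1:20), paste0("s", 1:n)))
    v["G0010", ] <- labels * 10 + rnorm(n, sd = 0.1)  # separates perfectly
    co <- expression_cohort(v, labels, "t")
    imp <- rf_ensemble_scores(co, seed = s)$mean_importance
    names(which.max(imp)) == "G0010"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("extraction honors forced size and recovers planted genes", {
  sim <- tiny_cohort(n = 40, n_genes = 60, n_informative = 5, seed = 5)
  co <- sim$cohorts[[1]]
  ens <- rf_ensemble_scores(co, seed = 5)
  forced <- extract_data_driven_classifier(ens, co, k_min = 5, k_max = 5)
  expect_length(forced$genes, 5L)
  expect_identical(forced$provenance, "data-driven")
  hits <- vapply(1:10, function(s) {
    sim <- tiny_cohort(n = 40, n_genes = 60, n_informative = 5, seed = s)
    co <- sim$cohorts[[1]]
    ens <- rf_ensemble_scores(co, seed = s)
    cl <- extract_data_driven_classifier(ens, co, k_min = 5, k_max = 15)
    all(sim$ground_truth$informative_genes %in% cl$genes)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("reduction is a contraction and leaves single genes untouched", {
  sim <- tiny_cohort(n = 40, n_genes = 60, seed = 6)
  co <- sim$cohorts[[1]]
  one <- gene_classifier("one", "G0001", "literature")
  red <- reduce_classifier(co, one)
  expect_identical(red$classifier$genes, "G0001")
  expect_length(red$report$mi_dropped, 0L)
  expect_length(red$report$vif_dropped, 0L)
  cl <- gene_classifier("many", rownames(co$values)[1:20], "literature")
  red2 <- suppressWarnings(reduce_classifier(co, cl, target_max = 8))
  expect_true(all(red2$classifier$genes %in% cl$genes))
  expect_lte(length(red2$classifier$genes), 8L)
  # repeated application changes nothing further than a second contraction
  red3 <- suppressWarnings(reduce_classifier(co, red2$classifier, target_max = 8))
  expect_true(all(red3$classifier$genes %in% red2$classifier$genes))
})

test_that("the VIF stage removes exactly one of a duplicated gene pair", {
  set.seed(7)
  n <- 30
  labels <- rep(c(0L, 1L), each = n / 2)
  v <- matrix(rnorm(5 * n), nrow = 5,
              dimnames = list(sprintf("G%04d", 1:5), paste0("s", 1:n)))
  v[1:2, ] <- v[1:2, ] + rep(labels * 2, each = 2)
  v["G0003", ] <- v["G0001", ]  # exact duplicate of G0001
  co <- expression_cohort(v, labels, "dup")
  # independent VIF oracle: R^2 of regressing the duplicate on the others is 1
  vif_oracle <- suppressWarnings(
    summary(lm(v["G0003", ] ~ t(v[c(1:2, 4:5), ]))))$r.squared
  expect_gt(1 / (1 - min(vif_oracle, 1 - 1e-12)), 10)
  red <- suppressWarnings(
    reduce_classifier(co, gene_classifier("d", rownames(v), "literature"),
                      theta_mi = 0))
  expect_equal(sum(c("G0001", "G0003") %in% red$classifier$genes), 1L)
  expect_equal(sum(c("G0001", "G0003") %in% red$report$vif_dropped), 1L)
})

test_that("logistic scores are probabilities with the expected AUC behavior", {
  set.seed(8)
  n <- 40
  labels <- rep(c(0L, 1L), each = n / 2)
  v <- matrix(rnorm(3 * n), nrow = 3,
              dimnames = list(sprintf("G%04d", 1:3), paste0("s", 1:n)))
  v["G0001", ] <- labels * 5 + rnorm(n, sd = 0.1)  # perfect separator
  co <- expression_cohort(v, labels, "sep")
  expect_warning(ls1 <- logistic_scores(co, gene_classifier("g1", "G0001",
                                                            "literature")),
                 "ridge")
  expect_equal(ls1$auc, 1.0)
  expect_true(all(ls1$scores >= 0 & ls1$scores <= 1))
  # null: labels independent of genes -> AUC near 0.5
  set.seed(9)
  n <- 200
  labels <- rep(c(0L, 1L), each = n / 2)
  v0 <- matrix(rnorm(4 * n), nrow = 4,
               dimnames = list(sprintf("G%04d", 1:4), paste0("s", 1:n)))
  co0 <- expression_cohort(v0, labels, "null")
  ls0 <- logistic_scores(co0, gene_classifier("all", rownames(v0),
                                              "literature"))
  expect_lt(abs(ls0$auc - 0.5), 0.1)
})

test_that("top10 refinement honors the size guard and recovers planted genes", {
  sim <- tiny_cohort(n = 40, n_genes = 60, n_informative = 5, seed = 10)
  co <- sim$cohorts[[1]]
  small <- gene_classifier("small", rownames(co$values)[1:8], "literature")
  expect_identical(top10_refine(co, small)$genes, small$genes)
  big <- gene_classifier("big", rownames(co$values)[1:30], "literature")
  refined <- top10_refine(co, big, seed = 10)
  expect_length(refined$genes, 10L)
  expect_identical(refined$provenance, "top10")
  hits <- vapply(1:10, function(s) {
    sim <- tiny_cohort(n = 40, n_genes = 60, n_informative = 5, seed = s + 40)
    co <- sim$cohorts[[1]]
    big <- gene_classifier("big", rownames(co$values)[1:30], "literature")
    all(sim$ground_truth$informative_genes %in%
          top10_refine(co, big, seed = s)$genes)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("union classifiers follow set algebra", {
  a <- gene_classifier("a", c("G0001", "G0002"), "top10")
  b <- gene_classifier("b", c("G0003", "G0004"), "top10")
  expect_identical(build_union(list(a, a))$genes, a$genes)
  expect_identical(build_union(list(a, b))$genes,
                   c("G0001", "G0002", "G0003", "G0004"))
  set.seed(11)
  for (i in 1:20) {
    lists <- lapply(1:3, function(j)
      gene_classifier(paste0("c", j),
                      sample(sprintf("G%04d", 1:15), sample(2:6, 1)), "top10"))
    u <- build_union(lists)
    sizes <- vapply(lists, function(cl) length(cl$genes), numeric(1))
    expect_lte(length(u$genes), sum(sizes))
    pairwise_disjoint <- all(table(unlist(lapply(lists, `[[`, "genes"))) == 1)
    expect_identical(length(u$genes) == sum(sizes), pairwise_disjoint)
  }
})

test_that("delta-AUC checks match an oracle recomputation", {
  sim <- tiny_cohort(n = 40, n_genes = 30, seed = 12)
  co <- sim$cohorts[[1]]
  cl <- gene_classifier("c", rownames(co$values)[1:10], "literature")
  red <- suppressWarnings(reduce_classifier(co, cl, target_max = 4))
  # identical full/reduced -> delta 0, passes
  same <- suppressWarnings(reduce_classifier(co, red$classifier))
  expect_equal(same$report$delta_auc, 0, tolerance = 1e-12)
  expect_true(delta_auc_check(same$report))
  expect_false(delta_auc_check(red$report, threshold = 0))
  # report delta matches brute-force pairwise AUC difference
  oracle <- auc_bruteforce(co$labels,
                           suppressWarnings(logistic_scores(co, cl))$scores) -
    auc_bruteforce(co$labels,
                   suppressWarnings(logistic_scores(co, red$classifier))$scores)
  expect_equal(red$report$delta_auc, oracle, tolerance = 1e-12)
})
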