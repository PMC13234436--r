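test_that("RFECV ranks are permutations and invariant to column order", {
  sim <- tiny_pathology(n_patients = c(20, 20), n_markers = 6, seed = 1)
  x <- nacstrat:::panel_feature_matrix(sim$table, "tumor")
  labels <- sim$table$patients$label
  r1 <- rfecv_rank(x, labels, base = "tree", seed = 3)
  expect_setequal(unname(r1$ranks), seq_len(ncol(x)))
  perm <- rev(seq_len(ncol(x)))
  r2 <- rfecv_rank(x[, perm], labels, base = "tree", seed = 3)
  expect_identical(r1$ranks[sort(names(r1$ranks))],
                   r2$ranks[sort(names(r2$ranks))])
  # single remaining feature gets rank 1
  r_one <- rfecv_rank(x[, 1, drop = FALSE], labels, base = "logistic")
  expect_equal(unname(r_one$ranks), 1L)
  expect_error(rfecv_rank(x, labels, k = 50L), "class count")
  expect_error(rfecv_rank(x, labels, base = "forest"))
})

test_that("planted predictive markers rank near the top", {
  hits <- vapply(1:20, function(s) {
    sim <- tiny_pathology(n_patients = c(40, 40), n_markers = 8,
                          n_predictive = 2, effect_size = 2, seed = s)
    x <- nacstrat:::panel_feature_matrix(sim$table, "tumor")
    labels <- sim$table$patients$label
    r <- rfecv_rank(x, labels, base = "logistic", seed = s)
    planted <- paste0(sim$ground_truth$predictive_markers$tumor, "__tumor")
    all(planted %in% r$ranking[1:3])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("pool construction is deterministic with the requested shape", {
  sim <- tiny_pathology(n_patients = c(30, 25), n_markers = 8, seed = 2)
  p1 <- build_pools(sim$table, n_pools = 3, seed = 5)
  p2 <- build_pools(sim$table, n_pools = 3, seed = 5)
  expect_identical(p1, p2)
  expect_length(p1, 3L)
  for (p in p1) {
    expect_length(p$tumor_markers, 5L)
    expect_length(p$stroma_markers, 5L)
    expect_false(anyDuplicated(nacstrat:::pool_features(p)) > 0)
  }
  # content deduplication: pools differ pairwise
  keys <- vapply(p1, function(p)
    paste(sort(nacstrat:::pool_features(p)), collapse = "|"), character(1))
  expect_false(any(duplicated(keys)))
  # strongly predictive markers are stable across pools
  counts <- table(unlist(lapply(p1, `[[`, "tumor_markers")))
  planted <- paste0(sim$ground_truth$predictive_markers$tumor, "__tumor")
  expect_gte(min(counts[planted]), 2)
})

test_that("stepwise selection honors sizes and degenerates correctly", {
  sim <- tiny_pathology(n_patients = c(30, 25), n_markers = 6, seed = 3)
  x <- nacstrat:::panel_feature_matrix(sim$table)
  labels <- sim$table$patients$label
  pool <- colnames(x)[1:5]
  # size = |pool| -> the whole pool, both directions
  fw <- forward_select(pool, 5, "tree", x, labels, seed = 4)
  bw <- backward_eliminate(pool, 5, "tree", x, labels, seed = 4)
  expect_setequal(fw$markers, pool)
  expect_setequal(bw$markers, pool)
  for (size in 2:5) {
    expect_length(forward_select(pool, size, "tree", x, labels,
                                 seed = 4)$markers, size)
    expect_length(backward_eliminate(pool, size, "tree", x, labels,
                                     seed = 4)$markers, size)
  }
  expect_error(forward_select(pool, 9, "tree", x, labels), "size")
  # a duplicated column contributes nothing: the tree criterion with the
  # duplicate present equals the criterion without it exactly
  xd <- cbind(x[, 1:4], x[, 2, drop = FALSE])
  colnames(xd)[5] <- "zdup"
  folds <- nacstrat:::stratified_folds(labels, 3L, 4)
  with_dup <- nacstrat:::cv_balanced_accuracy(xd, labels, colnames(xd), folds,
                                              "tree", seed = 4)
  without_dup <- nacstrat:::cv_balanced_accuracy(xd, labels, colnames(xd)[1:4],
                                                 folds, "tree", seed = 4)
  expect_equal(with_dup, without_dup, tolerance = 1e-12)
})

test_that("greedy panels approach the exhaustive best subset", {
  sim <- tiny_pathology(n_patients = c(30, 25), n_markers = 4,
                        n_predictive = 2, seed = 5)
  x <- nacstrat:::panel_feature_matrix(sim$table)  # 8 features
  labels <- sim$table$patients$label
  pool <- colnames(x)
  folds <- nacstrat:::stratified_folds(labels, 3L, 6)
  crit <- function(cols) nacstrat:::cv_balanced_accuracy(x, labels, cols,
                                                         folds, "tree",
                                                         seed = 6)
  for (size in c(2L, 3L)) {
    best_exh <- max(combn(pool, size, FUN = function(cols) crit(cols)))
    fw <- forward_select(pool, size, "tree", x, labels, seed = 6)
    bw <- backward_eliminate(pool, size, "tree", x, labels, seed = 6)
    expect_gte(crit(fw$markers), best_exh - 0.02)
    expect_gte(crit(bw$markers), best_exh - 0.02)
  }
})

test_that("panel evaluation is deterministic with depth-limited trees", {
  sim <- tiny_pathology(n_patients = c(30, 25), n_markers = 6, seed = 7)
  x <- nacstrat:::panel_feature_matrix(sim$table)
  labels <- sim$table$patients$label
  panel <- forward_select(colnames(x)[1:5], 3, "tree", x, labels, seed = 8)
  r1 <- evaluate_panel(panel, x, labels, seed = 8)
  r2 <- evaluate_panel(panel, x, labels, seed = 8)
  expect_identical(r1$mean_metrics, r2$mean_metrics)
  expect_length(r1$fold_metrics, 3L)
  expect_equal(r1$mean_metrics$accuracy,
               mean(vapply(r1$fold_metrics, `[[`, numeric(1), "accuracy")))
  # rpart trees respect the max depth of 3
  m <- nacstrat:::fit_base_model(x, labels, "tree")
  nodes <- as.numeric(rownames(m$fit$frame))
  expect_lte(max(floor(log2(nodes))), 3)  # node 2^d is at depth d
  # a perfectly separating marker yields mean accuracy 1
  xs <- x
  xs[, 1] <- labels * 10
  expect_equal(evaluate_panel(colnames(xs)[1], xs, labels,
                              seed = 8)$mean_metrics$accuracy, 1)
})

test_that("the panel search logs every configuration and picks the incumbent", {
  sim <- tiny_pathology(n_patients = c(30, 25), n_markers = 6,
                        n_predictive = 2, seed = 9)
  pools <- build_pools(sim$table, n_pools = 2, seed = 9)
  fit <- search_best_panel(sim$table, pools, sizes = 2:3, bases = "tree",
                           data_types = c("raw", "standardized"), seed = 9)
  expect_s3_class(fit, "nac_panel")
  expect_equal(nrow(fit$log), 2L * 2L * 1L * 2L * 2L)
  expect_equal(max(fit$log$balanced_accuracy), fit$result$balanced_accuracy)
  expect_true(fit$panel$size %in% 2:3)
  # singleton search equals that configuration's stepwise result
  single <- search_best_panel(sim$table, pools[1], sizes = 3, bases = "tree",
                              data_types = "raw", directions = "forward",
                              seed = 9)
  x <- nacstrat:::panel_feature_matrix(sim$table)
  direct <- forward_select(pools[[1]], 3, "tree", x,
                           sim$table$patients$label, seed = 9,
                           data_type = "raw")
  expect_identical(single$panel$markers, direct$markers)
  # predictions partition the patients
  grp <- predict(fit, sim$table)
  expect_length(grp, nrow(sim$table$patients))
  expect_true(all(grp %in% c("response", "nonresponse")))
})

test_that("the search recovers planted markers on planted data", {
  hits <- vapply(1:10, function(s) {
    sim <- tiny_pathology(n_patients = c(55, 36), n_markers = 12,
                          n_predictive = 2, effect_size = 2, seed = s + 10)
    pools <- build_pools(sim$table, n_pools = 2, seed = s)
    fit <- search_best_panel(sim$table, pools, sizes = 2:3,
                             bases = "tree", data_types = "standardized",
                             seed = s)
    planted <- c(paste0(sim$ground_truth$predictive_markers$tumor, "__tumor"),
                 paste0(sim$ground_truth$predictive_markers$stroma, "__stroma"))
    any(planted %in% fit$panel$markers)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
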