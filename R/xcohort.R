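# Multicohort cross-validation: gene-space harmonization, exhaustive run
# enumeration (train/validation/test role rotation x classifier variant x
# model), run execution, and the six evaluation metrics in closed form.

#' Harmonize gene spaces across cohorts
#'
#' Keeps genes present in every cohort whose scaled distributions agree
#' across cohorts: for each cohort pair a Welch two-sample t-test is run per
#' gene and the gene is retained only when p > alpha in every pair.
#' `alpha = 0` reduces to the presence filter alone.
#'
#' @param cohorts list of >= 2 [expression_cohort()] objects with scaled
#'   values.
#' @param alpha significance level of the exclusion test (default 0.05).
#' @return character vector of harmonized gene ids.
#' @export
harmonize <- function(cohorts, alpha = 0.05) {
  if (length(cohorts) < 2L)
    stop("harmonization requires at least two cohorts", call. = FALSE)
  genes <- Reduce(intersect, lapply(cohorts, function(co) rownames(co$values)))
  if (length(genes) == 0L)
    stop(sprintf("no shared genes; per-cohort counts: %s",
                 paste(vapply(cohorts, function(co) nrow(co$values),
                              numeric(1)), collapse = ", ")), call. = FALSE)
  if (alpha <= 0) return(genes)
  keep <- rep(TRUE, length(genes))
  pairs <- utils::combn(length(cohorts), 2)
  for (p in seq_len(ncol(pairs))) {
    a <- cohorts[[pairs[1, p]]]$values[genes, , drop = FALSE]
    b <- cohorts[[pairs[2, p]]]$values[genes, , drop = FALSE]
    keep <- keep & welch_p_values(a, b) > alpha
  }
  genes[keep]
}

# Vectorized per-gene Welch t-test between two genes x samples matrices.
welch_p_values <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # genes constant in both cohorts with equal means differ in no way
  p[se2 == 0 & ma == mb] <- 1
  p[se2 == 0 & ma != mb] <- 0
  p
}

#' Enumerate the full cross-validation design
#'
#' Every ordered (train, validation) pair of distinct cohorts — the remaining
#' cohorts are the test set — crossed with every classifier, variant and
#' model. With 4 cohorts, 17 classifiers, 2 variants and 3 models this is
#' 12 role assignments and 1,224 runs in total. Rows are sorted by
#' (classifier, variant, model, train, validation) for stable diffs.
#'
#' @param cohort_ids character vector of >= 2 unique cohort ids.
#' @param classifiers character vector of classifier names.
#' @param variants subset of c("top10", "union").
#' @param models subset of c("logistic", "tree", "forest").
#' @return a `run_matrix`: data.frame with columns `classifier`, `variant`,
#'   `model`, `train`, `validation`, `tests` (comma-separated), `run_id`.
#' @export
enumerate_runs <- function(cohort_ids,
                           classifiers,
                           variants = c("top10", "union"),
                           models = c("logistic", "tree", "forest")) {
  if (anyDuplicated(cohort_ids))
    stop_field("cohort_ids", "must be unique")
  if (length(cohort_ids) < 2L)
    stop_field("cohort_ids", "at least two cohorts are required")
  variants <- match.arg(variants, c("top10", "union"), several.ok = TRUE)
  models <- match.arg(models, c("logistic", "tree", "forest"),
                      several.ok = TRUE)
  roles <- expand.grid(validation = cohort_ids, train = cohort_ids,
                       stringsAsFactors = FALSE)
  roles <- roles[roles$train != roles$validation, c("train", "validation")]
  cvm <- expand.grid(model = models, variant = variants,
                     classifier = classifiers, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  grid <- cbind(
    roles[rep(seq_len(nrow(roles)), times = nrow(cvm)), , drop = FALSE],
    cvm[rep(seq_len(nrow(cvm)), each = nrow(roles)), , drop = FALSE])
  grid$tests <- vapply(seq_len(nrow(grid)), function(i)
    paste(setdiff(cohort_ids, c(grid$train[i], grid$validation[i])),
          collapse = ","), character(1))
  grid <- grid[order(grid$classifier, grid$variant, grid$model,
                     grid$train, grid$validation),
               c("classifier", "variant", "model", "train", "validation",
                 "tests")]
  rownames(grid) <- NULL
  grid$run_id <- seq_len(nrow(grid))
  class(grid) <- c("run_matrix", "data.frame")
  grid
}

#' @export
print.run_matrix <- function(x, ...) {
  cat(sprintf("<run_matrix> %d runs (%d classifiers x %d variants x %d models x %d role pairs)\n",
              nrow(x), length(unique(x$classifier)),
              length(unique(x$variant)), length(unique(x$model)),
              nrow(unique(x[, c("train", "validation")]))))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Execute one cross-validation run
#'
#' Fits the run's model on the training cohort only (classifier genes
#' intersected with the harmonized gene list) and scores every cohort role;
#' predictions threshold the score at 0.5.
#'
#' @param spec one row of a [enumerate_runs()] matrix (or an equivalent
#'   list with `train`, `validation`, `tests`, `model`, `classifier`).
#' @param cohorts named list of scaled [expression_cohort()] objects.
#' @param classifier a [gene_classifier()] (the variant the run names).
#' @param harmonized optional harmonized gene list to intersect with.
#' @param seed seed for the forest model.
#' @return a `run_result`: list with `spec`, `metrics` (named list of
#'   metric sets per role: train, validation, test1, test2, ...) and
#'   `scores` per cohort.
#' @export
execute_run <- function(spec, cohorts, classifier, harmonized = NULL,
                        seed = 1L) {
  genes <- classifier$genes
  if (!is.null(harmonized)) genes <- intersect(genes, harmonized)
  train <- cohorts[[spec$train]]
  genes <- intersect(genes, rownames(train$values))
  if (length(genes) == 0L)
    stop("classifier shares no genes with the harmonized space", call. = FALSE)
  model <- fit_base_model(t(train$values[genes, , drop = FALSE]),
                          train$labels, base = spec$model, seed = seed)
  tests <- if (is.null(spec$tests) || !nzchar(spec$tests)) character(0)
           else strsplit(spec$tests, ",", fixed = TRUE)[[1]]
  roles <- c(train = spec$train, validation = spec$validation)
  if (length(tests) > 0L)
    roles <- c(roles, stats::setNames(tests, paste0("test", seq_along(tests))))
  metrics <- list(); scores <- list()
  for (r in names(roles)) {
    co <- cohorts[[roles[[r]]]]
    g <- intersect(genes, rownames(co$values))
    sc <- model$predict(t(co$values[g, , drop = FALSE]))
    scores[[r]] <- stats::setNames(sc, colnames(co$values))
    metrics[[r]] <- compute_metrics(co$labels, sc)
  }
  structure(list(spec = spec, metrics = metrics, scores = scores,
                 genes_used = genes),
            class = "run_result")
}

#' Compute the six evaluation metrics from labels and scores
#'
#' Confusion counts come from thresholding the scores; accuracy, recall
#' (sensitivity for class R), precision, F1 and the Matthews correlation
#' coefficient follow their closed forms with the 0/0 -> 0 convention (F1 is
#' 0 when precision + recall = 0; MCC is 0 when any marginal is empty). AUC
#' is the tie-corrected Mann-Whitney statistic (mid-ranks).
#'
#' @param labels binary labels (0 = NR, 1 = R).
#' @param scores numeric scores, same length.
#' @param threshold classification threshold on the score (default 0.5).
#' @return a `metric_set` list: `accuracy`, `recall`, `precision`, `f1`,
#'   `mcc`, `auc` plus the confusion counts `tp`, `fp`, `fn`, `tn`. With
#'   single-class labels AUC is `NA` with a warning.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- check_binary_labels(labels, require_both = FALSE)
  if (length(scores) != length(labels))
    stop_field("scores", "length must match labels")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  n <- tp + fp + fn + tn
  accuracy <- (tp + tn) / n
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  auc <- auc_mann_whitney(labels, scores)
  structure(list(accuracy = accuracy, recall = recall, precision = precision,
                 f1 = f1, mcc = mcc, auc = auc,
                 tp = tp, fp = fp, fn = fn, tn = tn),
            class = "metric_set")
}

# Tie-corrected Mann-Whitney AUC via mid-ranks.
auc_mann_whitney <- function(labels, scores) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined for single-class labels", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("accuracy %.3f | recall %.3f | precision %.3f | f1 %.3f | mcc %+.3f | auc %s\n",
              x$accuracy, x$recall, x$precision, x$f1, x$mcc,
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  invisible(x)
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %s / %s / %s | train=%s validation=%s\n",
              x$spec$classifier, x$spec$variant, x$spec$model,
              x$spec$train, x$spec$validation))
  for (r in names(x$metrics)) {
    cat(sprintf("  %-11s", r)); print(x$metrics[[r]])
  }
  invisible(x)
}
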