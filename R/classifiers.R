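# Data-driven gene-classifier extraction and reduction: random-forest
# importance ensembles, top-k hierarchical-clustering selection, mutual
# information / VIF / clustering filters, and the top-10 / union variants.

#' Gene classifier container
#'
#' A named, ordered gene set with provenance (how it was obtained) and
#' optional per-gene importance weights.
#'
#' @param name classifier name.
#' @param genes character vector of unique gene ids (non-empty).
#' @param provenance one of "data-driven", "literature", "top10", "union",
#'   "reduced".
#' @param source_cohort optional originating cohort id.
#' @param weights optional named numeric importance weights.
#' @return an object of class `gene_classifier`.
#' @export
gene_classifier <- function(name, genes,
                            provenance = c("data-driven", "literature",
                                           "top10", "union", "reduced"),
                            source_cohort = NULL, weights = NULL) {
  provenance <- match.arg(provenance)
  genes <- as.character(genes)
  if (length(genes) == 0L) stop_field("genes", "must be non-empty")
  if (anyDuplicated(genes)) stop_field("genes", "must be unique")
  structure(list(name = name, genes = genes, provenance = provenance,
                 source_cohort = source_cohort, weights = weights),
            class = "gene_classifier")
}

#' @export
print.gene_classifier <- function(x, ...) {
  cat(sprintf("<gene_classifier '%s'> %d genes (%s)\n", x$name,
              length(x$genes), x$provenance))
  cat(" ", paste(utils::head(x$genes, 10), collapse = ", "),
      if (length(x$genes) > 10) "..." else "", "\n")
  invisible(x)
}

#' Random-forest ensemble scores and importances
#'
#' Fits `n_forests` random forests of `n_trees` trees each (forest f is
#' seeded with `seed + f`), designed for very small cohorts where a single
#' forest's importance ranking is unstable. Per-sample prediction scores are
#' the mean over forests of the out-of-bag vote fraction for class R, so the
#' scores are out-of-model rather than trivially perfect in-sample fits.
#' Per-gene importance is the mean decrease in Gini impurity averaged over
#' forests.
#'
#' @param cohort an [expression_cohort()] with >= 2 samples per class.
#' @param n_forests number of forests (default 10).
#' @param n_trees trees per forest (default 100).
#' @param seed integer seed.
#' @return an `ensemble_result`: list with `mean_scores` (per sample, in
#'   \[0, 1\]), `mean_importance` (per gene, >= 0), `n_forests`, `n_trees`,
#'   `seed`.
#' @export
rf_ensemble_scores <- function(cohort, n_forests = 10L, n_trees = 100L,
                               seed = 1L) {
  stopifnot(inherits(cohort, "expression_cohort"))
  tab <- table(factor(cohort$labels, levels = c(0L, 1L)))
  if (any(tab < 2L))
    stop("at least 2 samples per class are required", call. = FALSE)
  # genes in canonical (lexicographic) order so results do not depend on the
  # storage order of the input matrix
  gene_order <- order(rownames(cohort$values))
  x <- t(cohort$values[gene_order, , drop = FALSE])
  y <- factor(cohort$labels, levels = c(0L, 1L))
  scores <- matrix(0, nrow = ncol(cohort$values), ncol = n_forests)
  imp <- matrix(0, nrow = nrow(cohort$values), ncol = n_forests,
                dimnames = list(rownames(cohort$values)[gene_order], NULL))
  for (f in seq_len(n_forests)) {
    rf <- with_seed(seed + f, randomForest::randomForest(
      x = x, y = y, ntree = n_trees, importance = FALSE))
    scores[, f] <- rf$votes[, "1"]
    imp[, f] <- rf$importance[, "MeanDecreaseGini"]
  }
  structure(list(
    mean_scores = stats::setNames(rowMeans(scores), colnames(cohort$values)),
    mean_importance = rowMeans(imp),
    n_forests = as.integer(n_forests), n_trees = as.integer(n_trees),
    seed = as.integer(seed)), class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d forests x %d trees over %d genes\n",
              x$n_forests, x$n_trees, length(x$mean_importance)))
  cat("top genes:",
      paste(names(sort(x$mean_importance, decreasing = TRUE))[1:5],
            collapse = ", "), "\n")
  invisible(x)
}

# top-k genes by mean importance; ties broken lexicographically by gene id
top_k_genes <- function(importance, k) {
  ord <- order(-importance, names(importance))
  names(importance)[ord][seq_len(k)]
}

#' Extract a data-driven classifier by top-k cluster agreement
#'
#' Sweeps k over `[k_min, k_max]`: for each k the top-k genes by mean
#' ensemble importance are taken, samples are hierarchically clustered
#' (Ward, Euclidean) on the per-gene standardized k-gene submatrix, the
#' dendrogram is cut into two clusters, and the agreement between the cut and
#' the NR/R labels is scored by the adjusted Rand index. The top-k set of the
#' smallest k attaining the maximum agreement is returned.
#'
#' @param ensemble an `ensemble_result` from [rf_ensemble_scores()].
#' @param cohort the [expression_cohort()] the ensemble was fitted on.
#' @param k_min,k_max bounds of the sweep (defaults 5 and 30).
#' @param name classifier name.
#' @return a [gene_classifier()] with provenance "data-driven" and the
#'   per-gene importances as weights.
#' @export
extract_data_driven_classifier <- function(ensemble, cohort, k_min = 5L,
                                           k_max = 30L,
                                           name = "data-driven") {
  stopifnot(inherits(ensemble, "ensemble_result"),
            inherits(cohort, "expression_cohort"))
  if (k_min < 1L || k_min > k_max)
    stop_field("k_min", "need 1 <= k_min <= k_max")
  if (k_max > nrow(cohort$values))
    stop_field("k_max", "cannot exceed the gene count")
  scaled <- apply_scaler(cohort$values, "standard")$values
  best_k <- NA_integer_; best_ari <- -Inf
  for (k in k_min:k_max) {
    genes <- top_k_genes(ensemble$mean_importance, k)
    sub <- t(scaled[genes, , drop = FALSE])
    d <- stats::dist(sub, method = "euclidean")
    if (all(d == 0))
      stop("clustering degenerate: all samples identical", call. = FALSE)
    cut <- stats::cutree(stats::hclust(d, method = "ward.D2"), k = 2)
    ari <- mclust::adjustedRandIndex(cut, cohort$labels)
    if (ari > best_ari + 1e-12) { best_ari <- ari; best_k <- k }
  }
  genes <- top_k_genes(ensemble$mean_importance, best_k)
  gene_classifier(name, genes, provenance = "data-driven",
                  source_cohort = cohort$cohort_id,
                  weights = ensemble$mean_importance[genes])
}

# Plug-in mutual information (nats) between a quantile-binned gene and the
# binary labels; 4 bins by default.
mutual_information <- function(x, labels, bins = 4L) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE))
  if (length(qs) < 2L) return(0)
  bx <- cut(x, breaks = qs, include.lowest = TRUE)
  tab <- table(bx, labels)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  max(mi, 0)
}

# Variance inflation factors by OLS of each gene on the remaining genes
# (columns of x). Perfect collinearity (or p >= n) gives Inf.
vif_values <- function(x) {
  p <- ncol(x)
  if (p < 2L) return(stats::setNames(rep(1, p), colnames(x)))
  vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    tss <- sum((x[, j] - mean(x[, j]))^2)
    rss <- sum(fit$residuals^2)
    if (tss == 0) return(1)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(x))
}

#' Reduce a gene classifier by mutual information, VIF and clustering
#'
#' Three sequential filters applied to the power-scaled (Yeo-Johnson)
#' expression of the classifier genes:
#' \enumerate{
#'   \item drop genes whose label mutual information (plug-in estimate on
#'     4 quantile bins) is below `theta_mi`;
#'   \item iteratively drop the gene with the largest variance inflation
#'     factor while the maximum VIF exceeds `theta_vif` (ties: lower MI,
#'     then lexicographically later gene id);
#'   \item if more than `target_max` genes remain, cluster the genes
#'     (Ward, Euclidean on standardized expression profiles) into
#'     `target_max` clusters and keep the highest-MI gene per cluster.
#' }
#' If every gene would be filtered out, the single highest-MI gene is kept
#' with a warning. The report carries the drop lists and the difference in
#' ROC AUC between logistic scores of the full and reduced classifiers.
#'
#' @param cohort an [expression_cohort()].
#' @param classifier a [gene_classifier()] whose genes are present in the
#'   cohort.
#' @param target_max maximum size of the reduced classifier (default 10).
#' @param theta_mi MI threshold in nats (default 0.01).
#' @param theta_vif VIF threshold (default 10).
#' @return list with `classifier` (provenance "reduced") and `report`
#'   (a `reduction_report` with `mi_dropped`, `vif_dropped`,
#'   `cluster_dropped`, `auc_full`, `auc_reduced`, `delta_auc`).
#' @export
reduce_classifier <- function(cohort, classifier, target_max = 10L,
                              theta_mi = 0.01, theta_vif = 10) {
  stopifnot(inherits(cohort, "expression_cohort"),
            inherits(classifier, "gene_classifier"))
  missing_genes <- setdiff(classifier$genes, rownames(cohort$values))
  if (length(missing_genes) > 0L)
    stop(sprintf("classifier genes absent from cohort: %s",
                 paste(missing_genes, collapse = ", ")), call. = FALSE)
  genes <- classifier$genes
  scaled <- apply_scaler(cohort$values[genes, , drop = FALSE], "power")$values
  mi <- vapply(genes, function(g)
    mutual_information(scaled[g, ], cohort$labels), numeric(1))
  mi_dropped <- character(0); vif_dropped <- character(0)
  cluster_dropped <- character(0)
  keep <- genes
  if (length(keep) > 1L) {
    mi_dropped <- keep[mi[keep] < theta_mi]
    keep <- setdiff(keep, mi_dropped)
  }
  if (length(keep) == 0L) {
    warning("all genes fell below the MI threshold; keeping the top-MI gene",
            call. = FALSE)
    keep <- genes[which.max(mi)]
    mi_dropped <- setdiff(mi_dropped, keep)
  }
  while (length(keep) > 1L) {
    v <- vif_values(t(scaled[keep, , drop = FALSE]))
    if (max(v) <= theta_vif) break
    worst <- max(v)
    cand <- keep[v >= worst - 1e-12]
    # among maximal-VIF ties prefer dropping the least informative gene,
    # then the lexicographically later id
    cand <- cand[order(mi[cand], -rank(cand))]
    drop <- cand[1]
    vif_dropped <- c(vif_dropped, drop)
    keep <- setdiff(keep, drop)
  }
  if (length(keep) > target_max) {
    d <- stats::dist(scaled[keep, , drop = FALSE])
    cl <- stats::cutree(stats::hclust(d, method = "ward.D2"), k = target_max)
    reps <- vapply(split(keep, cl), function(g)
      g[order(-mi[g], g)][1], character(1))
    cluster_dropped <- setdiff(keep, reps)
    keep <- keep[keep %in% reps]
  }
  reduced <- gene_classifier(paste0(classifier$name, "_reduced"), keep,
                             provenance = "reduced",
                             source_cohort = cohort$cohort_id,
                             weights = mi[keep])
  auc_full <- logistic_scores(cohort, classifier)$auc
  auc_reduced <- logistic_scores(cohort, reduced)$auc
  report <- structure(list(
    input_size = length(genes), output_size = length(keep),
    mi_dropped = mi_dropped, vif_dropped = vif_dropped,
    cluster_dropped = cluster_dropped,
    auc_full = auc_full, auc_reduced = auc_reduced,
    delta_auc = auc_full - auc_reduced), class = "reduction_report")
  list(classifier = reduced, report = report)
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf("<reduction_report> %d -> %d genes (MI dropped %d, VIF %d, cluster %d)\n",
              x$input_size, x$output_size, length(x$mi_dropped),
              length(x$vif_dropped), length(x$cluster_dropped)))
  cat(sprintf("AUC full %.3f, reduced %.3f, delta %.3f\n",
              x$auc_full, x$auc_reduced, x$delta_auc))
  invisible(x)
}

#' Check that classifier reduction preserved discrimination
#'
#' @param report a `reduction_report` from [reduce_classifier()].
#' @param threshold maximum tolerated absolute AUC difference (default 0.2).
#' @return logical: TRUE when |delta AUC| < threshold.
#' @export
delta_auc_check <- function(report, threshold = 0.2) {
  stopifnot(inherits(report, "reduction_report"))
  abs(report$delta_auc) < threshold
}

#' In-cohort logistic prediction scores for a classifier
#'
#' Fits a maximum-likelihood logistic regression of the response on the
#' classifier genes; on complete separation (common on tiny cohorts) a
#' ridge-stabilized fit (penalty 1e-6) is used with a warning. Scores are
#' fitted probabilities in \[0, 1\].
#'
#' @param cohort an [expression_cohort()].
#' @param classifier a [gene_classifier()].
#' @return list with `scores` (named per-sample probabilities) and `auc`
#'   (tie-corrected Mann-Whitney AUC of scores vs labels).
#' @export
logistic_scores <- function(cohort, classifier) {
  stopifnot(inherits(cohort, "expression_cohort"),
            inherits(classifier, "gene_classifier"))
  genes <- intersect(classifier$genes, rownames(cohort$values))
  if (length(genes) == 0L)
    stop("no classifier genes present in the cohort", call. = FALSE)
  x <- t(cohort$values[genes, , drop = FALSE])
  fit <- fit_logistic(x, unname(cohort$labels))
  scores <- pmin(pmax(unname(fit$predict(x)), 0), 1)
  names(scores) <- colnames(cohort$values)
  list(scores = scores,
       auc = compute_metrics(cohort$labels, scores)$auc,
       separated = fit$separated)
}

#' Refine a classifier to at most its top 10 genes
#'
#' Classifiers with 10 or fewer genes are returned unchanged (provenance
#' retagged "top10"); larger classifiers are cut to the 10 genes with the
#' highest mean ensemble importance on the given cohort.
#'
#' @param cohort an [expression_cohort()].
#' @param classifier a [gene_classifier()].
#' @param seed seed forwarded to [rf_ensemble_scores()].
#' @param n_forests,n_trees ensemble size (defaults 10 and 100).
#' @return a [gene_classifier()] with provenance "top10".
#' @export
top10_refine <- function(cohort, classifier, seed = 1L, n_forests = 10L,
                         n_trees = 100L) {
  stopifnot(inherits(cohort, "expression_cohort"),
            inherits(classifier, "gene_classifier"))
  genes <- classifier$genes
  missing_genes <- setdiff(genes, rownames(cohort$values))
  if (length(missing_genes) > 0L)
    stop(sprintf("classifier genes absent from cohort: %s",
                 paste(missing_genes, collapse = ", ")), call. = FALSE)
  if (length(genes) <= 10L)
    return(gene_classifier(classifier$name, genes, provenance = "top10",
                           source_cohort = cohort$cohort_id,
                           weights = classifier$weights))
  sub <- expression_cohort(cohort$values[genes, , drop = FALSE],
                           cohort$labels, cohort$cohort_id)
  ens <- rf_ensemble_scores(sub, n_forests = n_forests, n_trees = n_trees,
                            seed = seed)
  top <- top_k_genes(ens$mean_importance, 10L)
  gene_classifier(classifier$name, top, provenance = "top10",
                  source_cohort = cohort$cohort_id,
                  weights = ens$mean_importance[top])
}

#' Union classifier from refined per-cohort variants
#'
#' Deduplicated union in first-seen order.
#'
#' @param refined non-empty list of [gene_classifier()] objects.
#' @param name classifier name (default from the first input).
#' @return a [gene_classifier()] with provenance "union".
#' @export
build_union <- function(refined, name = NULL) {
  if (length(refined) == 0L) stop("no classifiers supplied", call. = FALSE)
  genes <- unique(unlist(lapply(refined, function(cl) cl$genes)))
  if (is.null(name)) name <- paste0(refined[[1]]$name, "_union")
  gene_classifier(name, genes, provenance = "union")
}
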