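# Digital-pathology marker-panel optimization: RFECV feature ranking,
# 5 + 5 gene pools, forward/backward stepwise panel search over sizes 2-5
# with an incumbent-replacement rule, and threefold cross-validated
# evaluation. search_best_panel() is the package's central fitting function.

# Feature matrix (patients x features) for one compartment or both, with
# compartment-suffixed column names.
panel_feature_matrix <- function(table, compartment = c("both", "tumor", "stroma")) {
  compartment <- match.arg(compartment)
  tum <- table$tumor; colnames(tum) <- paste0(colnames(tum), "__tumor")
  str <- table$stroma; colnames(str) <- paste0(colnames(str), "__stroma")
  switch(compartment, both = cbind(tum, str), tumor = tum, stroma = str)
}

#' Recursive feature elimination with cross-validation (RFECV)
#'
#' Standard RFE semantics: starting from the full feature set, each round
#' removes the feature whose removal degrades the mean stratified k-fold
#' balanced accuracy least (i.e. the least important feature); the rank is
#' the reverse elimination order, so the last survivor has rank 1.
#' Deterministic given the seed (which fixes the fold assignment); ties are
#' broken by removing the lexicographically later feature id.
#'
#' @param x patients x features numeric matrix with column names.
#' @param labels binary response labels (0 = NR, 1 = R).
#' @param base base model: "tree" (gini, max depth 3) or "logistic".
#' @param k fold count (default 3); must not exceed the smallest class count.
#' @param seed integer seed for the fold assignment.
#' @return a `feature_ranking`: list with `ranking` (features ordered rank
#'   1..p), `ranks` (named integer vector), `base`, `k`, `seed`.
#' @export
rfecv_rank <- function(x, labels, base = c("tree", "logistic"), k = 3L,
                       seed = 1L) {
  base <- match.arg(base)
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop_field("x", "at least one feature is required")
  # canonical column order so the ranking is invariant to input layout
  x <- x[, order(colnames(x)), drop = FALSE]
  labels <- check_binary_labels(labels)
  folds <- stratified_folds(labels, k, seed)
  remaining <- colnames(x)
  eliminated <- character(0)
  while (length(remaining) > 1L) {
    perf_without <- vapply(remaining, function(f)
      cv_balanced_accuracy(x, labels, setdiff(remaining, f), folds, base,
                           seed = seed), numeric(1))
    # drop the feature whose absence leaves performance highest;
    # ties -> lexicographically later id removed first
    best <- remaining[order(-perf_without, -rank(remaining))][1]
    eliminated <- c(eliminated, best)
    remaining <- setdiff(remaining, best)
  }
  ranking <- c(remaining, rev(eliminated))
  structure(list(ranking = ranking,
                 ranks = stats::setNames(seq_along(ranking), ranking),
                 base = base, k = as.integer(k), seed = as.integer(seed)),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %d features, base = %s, %d-fold, seed %d\n",
              length(x$ranking), x$base, x$k, x$seed))
  cat("top:", paste(utils::head(x$ranking, 5), collapse = " > "), "\n")
  invisible(x)
}

#' Build candidate gene pools of 5 tumor + 5 stroma markers
#'
#' Pool i takes the top-5 tumor-compartment and top-5 stroma-compartment
#' markers from [rfecv_rank()] run with fold-assignment seed `seed + i - 1`;
#' pools are deduplicated by content and further seeds are consumed (up to
#' `5 * n_pools` in total) until `n_pools` distinct pools exist. If the seed
#' budget runs out, fewer pools are returned with a warning.
#'
#' @param table a `pathology_table`.
#' @param base base model for the rankings ("tree" or "logistic").
#' @param n_pools number of pools requested (default 10).
#' @param k fold count for the rankings (default 3).
#' @param seed integer base seed.
#' @return list of `gene_pool` objects: `tumor_markers`, `stroma_markers`
#'   (5 each, compartment-suffixed), `pool_id`, `seed`.
#' @export
build_pools <- function(table, base = "tree", n_pools = 10L, k = 3L,
                        seed = 1L) {
  stopifnot(inherits(table, "pathology_table"))
  if (ncol(table$tumor) < 5L)
    stop("at least 5 markers per compartment are required", call. = FALSE)
  labels <- table$patients$label
  tum <- panel_feature_matrix(table, "tumor")
  str <- panel_feature_matrix(table, "stroma")
  pools <- list(); seen <- character(0)
  s <- 0L
  while (length(pools) < n_pools && s < 5L * n_pools) {
    fold_seed <- seed + s
    s <- s + 1L
    top_t <- utils::head(rfecv_rank(tum, labels, base, k, fold_seed)$ranking, 5)
    top_s <- utils::head(rfecv_rank(str, labels, base, k, fold_seed)$ranking, 5)
    key <- paste(c(sort(top_t), sort(top_s)), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    pools[[length(pools) + 1L]] <- structure(
      list(tumor_markers = top_t, stroma_markers = top_s,
           pool_id = sprintf("pool%02d", length(pools) + 1L),
           seed = fold_seed),
      class = "gene_pool")
  }
  if (length(pools) < n_pools)
    warning(sprintf("only %d distinct pools found within the seed budget",
                    length(pools)), call. = FALSE)
  pools
}

#' @export
print.gene_pool <- function(x, ...) {
  cat(sprintf("<gene_pool %s> tumor: %s | stroma: %s\n", x$pool_id,
              paste(sub("__tumor$", "", x$tumor_markers), collapse = ", "),
              paste(sub("__stroma$", "", x$stroma_markers), collapse = ", ")))
  invisible(x)
}

pool_features <- function(pool) c(pool$tumor_markers, pool$stroma_markers)

# Floating refinement shared by both stepwise directions: hill-climb on
# single-marker swaps (selected <-> unselected) until no swap improves the
# criterion. Deterministic: swaps are scanned in lexicographic order and only
# strict improvements are taken.
refine_swaps <- function(selected, feats, x, labels, folds, base, seed,
                         max_pass = 10L) {
  crit <- function(cols) cv_balanced_accuracy(x, labels, cols, folds, base,
                                              seed = seed)
  current <- crit(selected)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (m in sort(selected)) {
      for (cand in sort(setdiff(feats, selected))) {
        trial <- c(setdiff(selected, m), cand)
        v <- crit(trial)
        if (v > current + 1e-12) {
          selected <- trial; current <- v; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  selected
}

marker_panel <- function(markers, base, data_type, direction, pool_id = NA) {
  structure(list(markers = markers, size = length(markers), base = base,
                 data_type = data_type, direction = direction,
                 pool_id = pool_id),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %d markers (%s, %s data, %s selection)\n",
              x$size, x$base, x$data_type, x$direction))
  cat(" ", paste(x$markers, collapse = ", "), "\n")
  invisible(x)
}

#' Forward stepwise panel selection within a pool
#'
#' Greedy addition: at each step the marker that maximizes the mean
#' threefold balanced accuracy when combined with the already-selected
#' markers is added, until `size` markers are selected; a floating
#' forward-backward refinement then hill-climbs on single-marker swaps until
#' no swap improves the criterion. Ties go to the lexicographically earlier
#' marker id. Folds are fixed by the seed across all candidate evaluations.
#'
#' @param pool a `gene_pool` (or character vector of feature names).
#' @param size panel size, between 2 and 5 and at most the pool size.
#' @param base "tree" or "logistic".
#' @param x patients x features matrix containing the pool features.
#' @param labels binary response labels.
#' @param seed fold seed.
#' @param data_type tag recorded on the panel ("raw" or "standardized").
#' @return a `marker_panel`.
#' @export
forward_select <- function(pool, size, base, x, labels, seed = 1L,
                           data_type = "raw") {
  feats <- if (inherits(pool, "gene_pool")) pool_features(pool) else pool
  if (size > length(feats)) stop_field("size", "cannot exceed the pool size")
  folds <- stratified_folds(labels, 3L, seed)
  selected <- character(0)
  while (length(selected) < size) {
    cand <- setdiff(feats, selected)
    crit <- vapply(cand, function(f)
      cv_balanced_accuracy(x, labels, c(selected, f), folds, base,
                           seed = seed), numeric(1))
    selected <- c(selected, cand[first_tie_break(crit, cand)])
  }
  if (size < length(feats))
    selected <- refine_swaps(selected, feats, x, labels, folds, base, seed)
  marker_panel(selected, base, data_type, "forward",
               if (inherits(pool, "gene_pool")) pool$pool_id else NA)
}

#' Backward stepwise panel elimination within a pool
#'
#' Mirror of [forward_select()]: starts from the full pool and removes, at
#' each step, the marker whose removal leaves the highest mean threefold
#' balanced accuracy, until `size` markers remain, followed by the same
#' floating swap refinement. The retained markers are reported in pool
#' order.
#'
#' @inheritParams forward_select
#' @return a `marker_panel`.
#' @export
backward_eliminate <- function(pool, size, base, x, labels, seed = 1L,
                               data_type = "raw") {
  feats <- if (inherits(pool, "gene_pool")) pool_features(pool) else pool
  if (size > length(feats)) stop_field("size", "cannot exceed the pool size")
  folds <- stratified_folds(labels, 3L, seed)
  selected <- feats
  while (length(selected) > size) {
    crit <- vapply(selected, function(f)
      cv_balanced_accuracy(x, labels, setdiff(selected, f), folds, base,
                           seed = seed), numeric(1))
    drop <- selected[first_tie_break(crit, selected)]
    selected <- setdiff(selected, drop)
  }
  if (size < length(feats))
    selected <- refine_swaps(selected, feats, x, labels, folds, base, seed)
  marker_panel(selected, base, data_type, "backward",
               if (inherits(pool, "gene_pool")) pool$pool_id else NA)
}

#' Threefold cross-validated evaluation of a marker panel
#'
#' Stratified 3-fold CV on the combined NAC + PCT table: per-fold and mean
#' metric sets ([compute_metrics()]), plus the mean balanced accuracy used as
#' the search criterion. A fold degenerating to a single class triggers one
#' refold with a shifted seed (with a warning); stratification makes this
#' rare.
#'
#' @param panel a `marker_panel` (or character vector of feature names).
#' @param x patients x features matrix.
#' @param labels binary response labels.
#' @param seed fold seed.
#' @return a `panel_result`: list with `panel`, `fold_metrics`,
#'   `mean_metrics`, `balanced_accuracy`, `seed`.
#' @export
evaluate_panel <- function(panel, x, labels, seed = 1L) {
  markers <- if (inherits(panel, "marker_panel")) panel$markers else panel
  base <- if (inherits(panel, "marker_panel")) panel$base else "tree"
  missing_m <- setdiff(markers, colnames(x))
  if (length(missing_m) > 0L)
    stop(sprintf("panel markers absent from data: %s",
                 paste(missing_m, collapse = ", ")), call. = FALSE)
  labels <- check_binary_labels(labels)
  for (attempt in 0:1) {
    folds <- stratified_folds(labels, 3L, seed + attempt)
    ok <- all(vapply(1:3, function(f)
      length(unique(labels[folds != f])) == 2L, logical(1)))
    if (ok) break
    warning("a fold lost one class; refolding with a shifted seed",
            call. = FALSE)
  }
  fold_fits <- lapply(1:3, function(f) {
    tr <- folds != f
    m <- fit_base_model(x[tr, markers, drop = FALSE], labels[tr], base,
                        seed = seed + f)
    sc <- m$predict(x[!tr, markers, drop = FALSE])
    list(metrics = suppressWarnings(compute_metrics(labels[!tr], sc)),
         bacc = balanced_accuracy(labels[!tr], as.integer(sc >= 0.5)))
  })
  fold_metrics <- lapply(fold_fits, `[[`, "metrics")
  metric_names <- c("accuracy", "recall", "precision", "f1", "mcc", "auc")
  mean_metrics <- lapply(stats::setNames(metric_names, metric_names),
                         function(mn) mean(vapply(fold_metrics, function(fm)
                           fm[[mn]], numeric(1)), na.rm = TRUE))
  bacc <- mean(vapply(fold_fits, `[[`, numeric(1), "bacc"))
  structure(list(panel = panel, fold_metrics = fold_metrics,
                 mean_metrics = mean_metrics, balanced_accuracy = bacc,
                 seed = as.integer(seed)),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat(sprintf("<panel_result> threefold CV, balanced accuracy %.3f\n",
              x$balanced_accuracy))
  cat(sprintf("mean: accuracy %.3f | f1 %.3f | mcc %+.3f | auc %.3f\n",
              x$mean_metrics$accuracy, x$mean_metrics$f1,
              x$mean_metrics$mcc, x$mean_metrics$auc))
  invisible(x)
}

#' Search for the best marker panel across pools, sizes, bases and data types
#'
#' The package's central fitting function. Iterates every combination of
#' gene pool, panel size (2-5), base model, selection direction (forward /
#' backward) and data type (raw / standardized), runs the stepwise selection,
#' evaluates the resulting panel by threefold cross-validation on the
#' combined NAC + PCT cohorts, and keeps the incumbent panel unless a
#' candidate achieves strictly higher mean balanced accuracy (ties: fewer
#' markers, then lexicographic panel). Balanced accuracy is used because the
#' two cohorts' class balances differ. The full search log is returned.
#'
#' @param table a raw `pathology_table` (standardized views are derived
#'   internally via [standardize_pathology()]).
#' @param pools list of `gene_pool` objects (e.g. from [build_pools()]).
#' @param sizes panel sizes to try (default 2:5).
#' @param bases base models (default c("tree", "logistic")).
#' @param data_types data representations (default c("raw", "standardized")).
#' @param directions selection directions (default both).
#' @param seed integer seed (folds).
#' @return an object of class `nac_panel`: the best `marker_panel`, its
#'   `panel_result`, the final model refitted on all patients, the search
#'   `log` (one row per configuration) and the data used.
#' @seealso [predict.nac_panel()], [stratify_predicted()]
#' @export
search_best_panel <- function(table, pools, sizes = 2:5,
                              bases = c("tree", "logistic"),
                              data_types = c("raw", "standardized"),
                              directions = c("forward", "backward"),
                              seed = 1L) {
  stopifnot(inherits(table, "pathology_table"), length(pools) > 0L)
  bases <- match.arg(bases, c("tree", "logistic"), several.ok = TRUE)
  data_types <- match.arg(data_types, c("raw", "standardized"),
                          several.ok = TRUE)
  directions <- match.arg(directions, c("forward", "backward"),
                          several.ok = TRUE)
  labels <- table$patients$label
  views <- list(raw = panel_feature_matrix(table))
  if ("standardized" %in% data_types)
    views$standardized <- panel_feature_matrix(standardize_pathology(table))
  best <- NULL; best_res <- NULL; best_crit <- -Inf
  log_rows <- list()
  for (pool in pools) for (size in sizes) for (base in bases)
    for (dt in data_types) for (dir in directions) {
      x <- views[[dt]]
      panel <- if (dir == "forward")
        forward_select(pool, size, base, x, labels, seed, data_type = dt)
      else backward_eliminate(pool, size, base, x, labels, seed,
                              data_type = dt)
      res <- suppressWarnings(evaluate_panel(panel, x, labels, seed))
      crit <- res$balanced_accuracy
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        pool_id = pool$pool_id, size = size, base = base, data_type = dt,
        direction = dir, balanced_accuracy = crit,
        markers = paste(panel$markers, collapse = ","),
        stringsAsFactors = FALSE)
      replace <- crit > best_crit + 1e-12 ||
        (abs(crit - best_crit) <= 1e-12 && !is.null(best) &&
           (panel$size < best$size ||
              (panel$size == best$size &&
                 paste(sort(panel$markers), collapse = ",") <
                   paste(sort(best$markers), collapse = ","))))
      if (is.null(best) || replace) {
        best <- panel; best_res <- res; best_crit <- crit
      }
    }
  x_best <- views[[best$data_type]]
  final_model <- fit_base_model(x_best[, best$markers, drop = FALSE],
                                labels, best$base, seed = seed)
  structure(list(panel = best, result = best_res, model = final_model,
                 log = do.call(rbind, log_rows), seed = as.integer(seed),
                 labels = labels, features = x_best[, best$markers,
                                                    drop = FALSE]),
            class = "nac_panel")
}

#' @export
print.nac_panel <- function(x, ...) {
  cat("Marker-panel model for NAC response prediction\n")
  print(x$panel)
  cat(sprintf("threefold CV balanced accuracy: %.3f (search over %d configurations)\n",
              x$result$balanced_accuracy, nrow(x$log)))
  invisible(x)
}

#' @export
summary.nac_panel <- function(object, ...) {
  cat("Marker-panel model for NAC response prediction\n\n")
  print(object$panel)
  cat("\nThreefold cross-validated performance:\n")
  print(object$result)
  cat("\nSearch space:", nrow(object$log), "configurations;",
      "top 5 by balanced accuracy:\n")
  lg <- object$log[order(-object$log$balanced_accuracy), ]
  print(utils::head(lg, 5), row.names = FALSE)
  invisible(object)
}

#' Predict NAC response groups from a fitted panel model
#'
#' @param object an `nac_panel` from [search_best_panel()].
#' @param newdata a `pathology_table` or a patients x features matrix with
#'   the panel's (compartment-suffixed) marker columns; defaults to the
#'   training table.
#' @param type "group" (predicted "response"/"nonresponse") or "score"
#'   (probability of response).
#' @param ... unused.
#' @return named vector of groups or scores.
#' @export
predict.nac_panel <- function(object, newdata = NULL,
                              type = c("group", "score"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$features
  else if (inherits(newdata, "pathology_table")) {
    tbl <- if (object$panel$data_type == "standardized" &&
                 newdata$data_type == "raw")
      standardize_pathology(newdata) else newdata
    panel_feature_matrix(tbl)[, object$panel$markers, drop = FALSE]
  } else as.matrix(newdata)[, object$panel$markers, drop = FALSE]
  sc <- object$model$predict(x)
  names(sc) <- rownames(x)
  if (type == "score") return(sc)
  stats::setNames(ifelse(sc >= 0.5, "response", "nonresponse"), rownames(x))
}

#' Plot the search criterion profile of a fitted panel model
#'
#' Balanced accuracy of every searched configuration, grouped by panel size,
#' with the selected panel highlighted.
#'
#' @param x an `nac_panel`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.nac_panel <- function(x, ...) {
  lg <- x$log
  graphics::plot(jitter(lg$size, 0.15), lg$balanced_accuracy,
                 xlab = "panel size", ylab = "3-fold balanced accuracy",
                 main = "Marker-panel search profile", pch = 19,
                 col = grDevices::grey(0.6), ...)
  graphics::points(x$panel$size, x$result$balanced_accuracy, pch = 17,
                   col = "firebrick", cex = 1.5)
  graphics::legend("bottomright", legend = "selected panel", pch = 17,
                   col = "firebrick", bty = "n")
  invisible(x)
}
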