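# Nine per-gene expression scalers, the Gaussianity gate, and random-forest
# premodeling that picks the working scaler for the multicohort stage.

#' The nine supported scaling methods
#'
#' Fixed method-name order used for deterministic tie-breaking.
#' @return character vector of method names.
#' @export
scaler_methods <- function() {
  c("log2", "log2_minmax", "standard", "minmax", "max_abs", "robust",
    "power", "quantile", "rankgauss")
}

# Yeo-Johnson transform for a fixed lambda.
yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else out[pos] <- log1p(x[pos])
  if (abs(lambda - 2) > 1e-10) {
    out[!pos] <- -((-x[!pos] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else out[!pos] <- -log1p(-x[!pos])
  out
}

# Profile log-likelihood of the Yeo-Johnson lambda under Gaussian errors:
# -n/2 log sigma^2(lambda) + (lambda - 1) * sum(sign(x) log(|x| + 1)).
yj_loglik <- function(lambda, x) {
  y <- yeo_johnson(x, lambda)
  s2 <- mean((y - mean(y))^2)
  if (!is.finite(s2) || s2 <= 0) return(-Inf)
  -length(x) / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

# Maximum-likelihood lambda by one-dimensional search on [-5, 5].
yj_fit_lambda <- function(x) {
  if (stats::sd(x) == 0) return(1)
  stats::optimize(function(l) yj_loglik(l, x),
                  interval = c(-5, 5), maximum = TRUE, tol = 1e-6)$maximum
}

rank_gauss <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 0.5) / n)
}

# Quantile transform to a standard-normal target on a fixed grid of
# `n_quantiles` levels with linear interpolation between empirical quantiles.
quantile_normal <- function(x, n_quantiles = 100L) {
  if (stats::sd(x) == 0) return(rep(0, length(x)))
  probs <- seq(0, 1, length.out = min(n_quantiles, length(x)))
  qs <- stats::quantile(x, probs = probs, names = FALSE, type = 7)
  u <- stats::approx(qs, probs, xout = x, ties = "ordered", rule = 2)$y
  eps <- 1e-7
  stats::qnorm(pmin(pmax(u, eps), 1 - eps))
}

scale_gene <- function(x, method) {
  switch(method,
    log2 = log2(x + 1),
    log2_minmax = {
      y <- log2(x + 1)
      rng <- range(y)
      if (diff(rng) == 0) rep(0.5, length(y)) else (y - rng[1]) / diff(rng)
    },
    standard = {
      s <- stats::sd(x)
      if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
    },
    minmax = {
      rng <- range(x)
      if (diff(rng) == 0) rep(0.5, length(x)) else (x - rng[1]) / diff(rng)
    },
    max_abs = {
      m <- max(abs(x))
      if (m == 0) x else x / m
    },
    robust = {
      iqr <- stats::IQR(x)
      if (iqr == 0) rep(0, length(x)) else (x - stats::median(x)) / iqr
    },
    power = {
      lambda <- yj_fit_lambda(x)
      y <- yeo_johnson(x, lambda)
      s <- stats::sd(y)
      if (s == 0) rep(0, length(y)) else (y - mean(y)) / s
    },
    quantile = quantile_normal(x),
    rankgauss = rank_gauss(x),
    stop(sprintf("unknown scaler method: %s", method), call. = FALSE)
  )
}

#' Apply one of the nine expression scalers
#'
#' All transforms are fitted and applied per gene (matrix row). `standard`
#' yields per-gene mean 0 / sd 1; `minmax` maps to \[0, 1\]; `power` is the
#' Yeo-Johnson transform with lambda fitted per gene by maximum likelihood,
#' then z-scored; `rankgauss` maps mid-ranks through (r - 0.5)/n and the
#' standard-normal quantile function; `quantile` maps values to standard
#' normal quantiles via a fixed 100-point empirical-quantile grid; `log2`
#' uses pseudocount 1 and `log2_minmax` is minmax after log2. Constant genes
#' become 0 (`standard`, `robust`) or 0.5 (`minmax`, `log2_minmax`), with a
#' warning.
#'
#' @param matrix numeric genes x samples matrix (or an [expression_cohort()]).
#' @param method one of [scaler_methods()].
#' @param fit_scope tag recorded on the result: "per-cohort" (default) or
#'   "pooled"; see [scale_cohorts()] for multi-cohort fitting.
#' @return a `scaled_matrix`: list with `values`, `method`, `fit_scope`.
#' @export
apply_scaler <- function(matrix, method, fit_scope = "per-cohort") {
  if (inherits(matrix, "expression_cohort")) matrix <- matrix$values
  matrix <- as.matrix(matrix)
  method <- match.arg(method, scaler_methods())
  if (!all(is.finite(matrix)))
    stop_field("matrix", "all values must be finite")
  if (method %in% c("log2", "log2_minmax") && any(matrix < 0))
    stop("log2 scaling requires non-negative values", call. = FALSE)
  const <- apply(matrix, 1, function(x) max(x) == min(x))
  if (any(const) && method %in% c("standard", "minmax", "robust", "log2_minmax"))
    warning(sprintf("%d constant gene(s) mapped to a constant under '%s'",
                    sum(const), method), call. = FALSE)
  out <- t(apply(matrix, 1, scale_gene, method = method))
  dimnames(out) <- dimnames(matrix)
  stopifnot(all(is.finite(out)))
  structure(list(values = out, method = method, fit_scope = fit_scope),
            class = "scaled_matrix")
}

#' Scale every cohort with one method
#'
#' Fitted per cohort by default (each dataset is rescaled independently to
#' remove cross-platform location/scale differences); `fit_scope = "pooled"`
#' fits one transform on the column-concatenated matrix over the shared genes.
#'
#' @param cohorts list of [expression_cohort()] objects.
#' @param method one of [scaler_methods()].
#' @param fit_scope "per-cohort" or "pooled".
#' @return list of [expression_cohort()] objects with scaled values.
#' @export
scale_cohorts <- function(cohorts, method, fit_scope = c("per-cohort", "pooled")) {
  fit_scope <- match.arg(fit_scope)
  if (fit_scope == "per-cohort")
    return(lapply(cohorts, function(co)
      expression_cohort(apply_scaler(co$values, method)$values,
                        co$labels, co$cohort_id)))
  genes <- Reduce(intersect, lapply(cohorts, function(co) rownames(co$values)))
  pooled <- do.call(cbind, lapply(cohorts, function(co)
    co$values[genes, , drop = FALSE]))
  scaled <- apply_scaler(pooled, method, fit_scope = "pooled")$values
  offsets <- cumsum(c(0, vapply(cohorts, function(co) ncol(co$values),
                                numeric(1))))
  lapply(seq_along(cohorts), function(i)
    expression_cohort(scaled[, (offsets[i] + 1):offsets[i + 1], drop = FALSE],
                      cohorts[[i]]$labels, cohorts[[i]]$cohort_id))
}

#' Gaussianity gate over scaled matrices
#'
#' Retains the methods whose scaled output looks Gaussian gene-wise: the mean
#' absolute per-gene skewness must not exceed `tau_skew` and the mean absolute
#' per-gene excess kurtosis must not exceed `tau_kurt`. Constant genes
#' contribute 0 to both means. Deterministic.
#'
#' @param matrices named list of `scaled_matrix` objects (one per method,
#'   all derived from the same input).
#' @param tau_skew,tau_kurt gate thresholds (defaults 0.5 and 1.0).
#' @return character vector of passing method names, in [scaler_methods()]
#'   order.
#' @export
gaussianity_gate <- function(matrices, tau_skew = 0.5, tau_kurt = 1.0) {
  if (length(matrices) == 0L) stop("no scaled matrices supplied", call. = FALSE)
  stats_for <- function(sm) {
    v <- sm$values
    sk <- apply(v, 1, function(x)
      if (stats::sd(x) == 0) 0 else abs(e1071::skewness(x, type = 2)))
    ku <- apply(v, 1, function(x)
      if (stats::sd(x) == 0) 0 else abs(e1071::kurtosis(x, type = 2)))
    c(skew = mean(sk), kurt = mean(ku))
  }
  res <- vapply(matrices, stats_for, numeric(2))
  pass <- names(matrices)[res["skew", ] <= tau_skew & res["kurt", ] <= tau_kurt]
  intersect(scaler_methods(), pass)
}

#' Random-forest premodeling to select the working scaler
#'
#' For every gated method, scales each cohort, fits a random forest on each
#' (cohort, classifier) combination, and evaluates accuracy, recall,
#' precision, F1 and MCC from the forest's out-of-bag votes. The method with
#' the highest mean MCC wins (ties: higher mean F1, then fixed
#' [scaler_methods()] order).
#'
#' @param cohorts list of [expression_cohort()] objects (>= 2).
#' @param classifiers list of [gene_classifier()] objects.
#' @param methods candidate method names (normally the gate's output).
#' @param seed integer seed.
#' @param n_trees trees per forest (default 100).
#' @return a `scaler_report`: list with `scores` (method x metric matrix),
#'   `gated_methods`, `selected`.
#' @export
premodel_select_scaler <- function(cohorts, classifiers, methods, seed = 1L,
                                   n_trees = 100L) {
  if (length(cohorts) < 2L)
    stop("premodeling requires at least two cohorts", call. = FALSE)
  methods <- match.arg(methods, scaler_methods(), several.ok = TRUE)
  metric_names <- c("accuracy", "recall", "precision", "f1", "mcc")
  scores <- matrix(NA_real_, nrow = length(methods), ncol = length(metric_names),
                   dimnames = list(methods, metric_names))
  for (m in methods) {
    scaled <- scale_cohorts(cohorts, m)
    combo <- matrix(NA_real_, nrow = 0, ncol = length(metric_names))
    for (co in scaled) {
      for (cl in classifiers) {
        genes <- intersect(cl$genes, rownames(co$values))
        if (length(genes) == 0L) {
          warning(sprintf("classifier '%s' shares no genes with cohort '%s'; skipped",
                          cl$name, co$cohort_id), call. = FALSE)
          next
        }
        rf <- with_seed(seed, randomForest::randomForest(
          x = t(co$values[genes, , drop = FALSE]),
          y = factor(co$labels, levels = c(0L, 1L)), ntree = n_trees))
        oob <- rf$votes[, "1"]
        ms <- compute_metrics(co$labels, oob)
        combo <- rbind(combo, unlist(ms[metric_names]))
      }
    }
    if (nrow(combo) == 0L)
      stop("all (cohort, classifier) combinations were skipped", call. = FALSE)
    scores[m, ] <- colMeans(combo)
  }
  ord <- order(-scores[, "mcc"], -scores[, "f1"],
               match(methods, scaler_methods()))
  structure(list(scores = scores, gated_methods = methods,
                 selected = methods[ord[1]]),
            class = "scaler_report")
}

#' @export
print.scaler_report <- function(x, ...) {
  cat("<scaler_report> premodeling over", length(x$gated_methods),
      "gated method(s)\n")
  print(round(x$scores, 4))
  cat("selected:", x$selected, "\n")
  invisible(x)
}
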