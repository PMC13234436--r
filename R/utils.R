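# Internal helpers shared across modules.

#' @keywords internal
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_binary_labels <- function(labels, require_both = TRUE) {
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop_field("labels", "must be binary 0 (NR) / 1 (R) with no missing values")
  if (require_both && length(unique(labels)) < 2L)
    stop_field("labels", "both classes (NR and R) must be present")
  labels
}

# Stratified k-fold assignment; returns integer fold id per sample.
# Deterministic given seed; each class is spread as evenly as possible.
stratified_folds <- function(labels, k, seed) {
  labels <- as.integer(labels)
  if (k > min(table(labels)))
    stop(sprintf("k = %d exceeds the smallest class count (%d)",
                 k, min(table(labels))), call. = FALSE)
  with_seed(seed, {
    folds <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
  })
}

# Run expr with the RNG seeded, restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  state <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

balanced_accuracy <- function(labels, pred) {
  labels <- as.integer(labels); pred <- as.integer(pred)
  sens <- if (any(labels == 1L)) mean(pred[labels == 1L] == 1L) else NA_real_
  spec <- if (any(labels == 0L)) mean(pred[labels == 0L] == 0L) else NA_real_
  mean(c(sens, spec), na.rm = TRUE)
}

# Penalised IRLS logistic fit used as a fallback when glm() meets complete
# separation on tiny cohorts; ridge 1e-6 keeps coefficients finite and the
# fit deterministic. x: n x p matrix (no intercept column), y in {0,1}.
ridge_logistic <- function(x, y, lambda = 1e-6, maxit = 100L, tol = 1e-10) {
  x <- cbind(`(Intercept)` = 1, as.matrix(x))
  p <- ncol(x)
  beta <- numeric(p)
  pen <- diag(lambda, p); pen[1, 1] <- 0  # intercept unpenalised
  for (it in seq_len(maxit)) {
    eta <- drop(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    xtw <- t(x * w)
    beta_new <- tryCatch(
      solve(xtw %*% x + pen, xtw %*% z),
      error = function(e) qr.solve(xtw %*% x + pen + diag(1e-8, p), xtw %*% z))
    beta_new <- drop(beta_new)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  structure(list(coefficients = stats::setNames(beta, colnames(x)),
                 lambda = lambda),
            class = "nacstrat_ridge_logistic")
}

predict_ridge_logistic <- function(fit, x) {
  x <- cbind(1, as.matrix(x))
  drop(1 / (1 + exp(-x %*% fit$coefficients)))
}

# Logistic fit with automatic ridge fallback on separation / non-convergence.
# Returns list(predict = function(newx) prob, separated = logical).
fit_logistic <- function(x, y) {
  x <- as.matrix(x)
  df <- data.frame(x, check.names = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = cbind(df, y = y), family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  # complete separation also shows as non-overlapping linear predictors even
  # when glm() converges just inside its warning threshold
  if (!separated && all(c(0, 1) %in% y)) {
    eta <- stats::predict(fit)
    if (min(eta[y == 1]) > max(eta[y == 0])) separated <- TRUE
  }
  if (separated || anyNA(stats::coef(fit))) {
    rfit <- ridge_logistic(x, y)
    warning("logistic fit met separation; ridge-stabilized estimate used",
            call. = FALSE)
    return(list(predict = function(newx) predict_ridge_logistic(rfit, newx),
                separated = TRUE, coefficients = rfit$coefficients))
  }
  list(predict = function(newx) {
         nd <- data.frame(as.matrix(newx), check.names = FALSE)
         colnames(nd) <- colnames(df)
         stats::predict(fit, newdata = nd, type = "response")
       },
       separated = FALSE, coefficients = stats::coef(fit))
}

# Shared base-model fit/predict used by cross-validation stages.
# base: "logistic" | "tree" | "forest". Trees use gini, max depth 3,
# min leaf 2 (deterministic); forests use 100 trees seeded per call.
fit_base_model <- function(x, y, base = c("logistic", "tree", "forest"),
                           seed = 1L, n_trees = 100L) {
  base <- match.arg(base)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (base == "logistic") {
    f <- suppressWarnings(fit_logistic(x, y))
    return(list(base = base,
                predict = function(newx) unname(f$predict(as.matrix(newx))),
                fit = f))
  }
  if (base == "tree") {
    df <- data.frame(x, check.names = FALSE)
    df$.y <- factor(y, levels = c(0L, 1L))
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = 3, minbucket = 2, minsplit = 4,
                          cp = 0, xval = 0))
    return(list(base = base,
                predict = function(newx) {
                  nd <- data.frame(as.matrix(newx), check.names = FALSE)
                  colnames(nd) <- colnames(df)[seq_len(ncol(x))]
                  unname(stats::predict(fit, newdata = nd)[, "1"])
                },
                fit = fit))
  }
  fit <- with_seed(seed,
    randomForest::randomForest(x = x, y = factor(y, levels = c(0L, 1L)),
                               ntree = n_trees))
  list(base = base,
       predict = function(newx)
         unname(stats::predict(fit, newdata = as.matrix(newx),
                               type = "prob")[, "1"]),
       fit = fit)
}

# Mean k-fold balanced accuracy of a base model on feature columns `cols`.
# Folds are supplied (fixed across comparisons for determinism).
cv_balanced_accuracy <- function(x, labels, cols, folds, base, seed = 1L) {
  accs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f; te <- !tr
    if (length(unique(labels[tr])) < 2L) return(NA_real_)
    m <- fit_base_model(x[tr, cols, drop = FALSE], labels[tr], base,
                        seed = seed + f)
    pred <- as.integer(m$predict(x[te, cols, drop = FALSE]) >= 0.5)
    balanced_accuracy(labels[te], pred)
  }, numeric(1))
  mean(accs, na.rm = TRUE)
}

first_tie_break <- function(score, ids) {
  # highest score wins; ties broken by lexicographic id
  ord <- order(-score, ids)
  ord[1L]
}
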