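# Clinical-style evaluation: heuristic dichotomization, univariate odds
# ratios, backward-stepwise multivariate logistic selection, marker-ratio
# comparisons, and Kaplan-Meier / log-rank analysis of predicted groups.

#' Heuristic cutoff by maximally selected chi-square
#'
#' Scans every midpoint between adjacent distinct observed values and picks
#' the cutoff that maximizes the 2x2 chi-square statistic of
#' (high/low) x (R/NR); ties go to the smaller cutoff. Deterministic. Note
#' that a univariate test performed at a cutoff selected this way is
#' anti-conservative (the selection inflates the type-I error); the package
#' documents rather than corrects this, matching common clinical practice.
#'
#' @param values numeric marker values (>= 2 distinct values).
#' @param labels binary response labels (0 = NR, 1 = R).
#' @return list with `cutoff`, `chi_square`, and `table` (a
#'   `contingency_table` with counts a = high/R, b = high/NR, c = low/R,
#'   d = low/NR).
#' @export
heuristic_cutoff <- function(values, labels) {
  labels <- check_binary_labels(labels)
  u <- sort(unique(values))
  if (length(u) < 2L)
    stop("all values identical; no cutoff exists", call. = FALSE)
  cand <- (u[-length(u)] + u[-1]) / 2
  chi <- vapply(cand, function(ct) chisq_2x2(values >= ct, labels), numeric(1))
  best <- which(chi >= max(chi) - 1e-12)[1]  # ties -> smaller cutoff
  ct <- cand[best]
  high <- values >= ct
  tab <- contingency_table(a = sum(high & labels == 1L),
                           b = sum(high & labels == 0L),
                           c = sum(!high & labels == 1L),
                           d = sum(!high & labels == 0L),
                           cutoff = ct)
  list(cutoff = ct, chi_square = chi[best], table = tab)
}

# Pearson chi-square (no continuity correction) of a binary exposure vs
# binary labels; degenerate margins give 0.
chisq_2x2 <- function(exposure, labels) {
  a <- sum(exposure & labels == 1L); b <- sum(exposure & labels == 0L)
  c_ <- sum(!exposure & labels == 1L); d <- sum(!exposure & labels == 0L)
  n <- a + b + c_ + d
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  if (denom == 0) return(0)
  n * (a * d - b * c_)^2 / denom
}

#' 2x2 contingency table for a dichotomized marker
#'
#' @param a,b,c,d counts for (high, R), (high, NR), (low, R), (low, NR).
#' @param marker optional marker id.
#' @param cutoff optional cutoff used.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, marker = NA_character_,
                              cutoff = NA_real_) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop_field("counts", "must be >= 0")
  structure(list(a = a, b = b, c = c, d = d, marker = marker,
                 cutoff = cutoff, n = sum(counts)),
            class = "contingency_table")
}

#' Univariate odds ratio with Wald confidence interval
#'
#' OR = (a d)/(b c) for the (high/low) x (R/NR) table. When any cell is 0 the
#' Haldane-Anscombe correction (0.5 added to every cell) is applied and
#' flagged. The 95% CI is Wald on the log scale; the p-value is the Pearson
#' chi-square (1 df, no continuity correction) of the uncorrected counts.
#'
#' @param table a [contingency_table()].
#' @param conf_level confidence level (default 0.95).
#' @return an `or_result`: `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `correction_applied`.
#' @export
univariate_or <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  correction <- any(c(a, b, c_, d) == 0)
  if (correction) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  chi <- chisq_2x2(rep(c(TRUE, FALSE), c(table$a + table$b, table$c + table$d)),
                   rep(c(1L, 0L, 1L, 0L), c(table$a, table$b, table$c, table$d)))
  structure(list(odds_ratio = or,
                 ci_low = or * exp(-z * se), ci_high = or * exp(z * se),
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 correction_applied = correction),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f), p = %.4g%s\n", x$odds_ratio,
              x$ci_low, x$ci_high, x$p_value,
              if (x$correction_applied) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Backward-stepwise multivariate logistic selection
#'
#' Fits the full logistic model and iteratively removes the predictor with
#' the largest Wald p-value until every remaining predictor has p < alpha.
#' `alpha = 1` returns the full model unchanged; an empty final model is
#' allowed. Non-convergent or separated fits fall back to a ridge-stabilized
#' estimate with a warning (p-values from the ridge fit's Wald statistics are
#' then approximate).
#'
#' @param predictors patients x predictors numeric matrix with column names.
#' @param labels binary response labels.
#' @param alpha retention threshold on the Wald p-value (default 0.05).
#' @return a `stepwise_logistic`: list with `retained` (predictor names),
#'   `dropped` (in removal order), `coefficients`, `or_table` (data.frame
#'   with OR, 95% CI and p per retained predictor), `alpha`.
#' @export
backward_stepwise_logistic <- function(predictors, labels, alpha = 0.05) {
  predictors <- as.matrix(predictors)
  labels <- check_binary_labels(labels)
  if (nrow(predictors) <= ncol(predictors))
    stop("more predictors than observations", call. = FALSE)
  current <- colnames(predictors)
  dropped <- character(0)
  wald <- function(cols) {
    if (length(cols) == 0L) return(NULL)
    df <- data.frame(predictors[, cols, drop = FALSE], check.names = FALSE)
    df$.y <- labels
    fit <- tryCatch(
      suppressWarnings(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial())),
      error = function(e) NULL)
    cf <- if (!is.null(fit) && fit$converged && !anyNA(stats::coef(fit)))
      summary(fit)$coefficients
    else {
      warning("stepwise fit did not converge; ridge-stabilized refit used",
              call. = FALSE)
      rf <- ridge_logistic(predictors[, cols, drop = FALSE], labels,
                           lambda = 1e-3)
      # approximate Wald from the penalised information matrix
      xm <- cbind(1, predictors[, cols, drop = FALSE])
      eta <- drop(xm %*% rf$coefficients)
      mu <- 1 / (1 + exp(-eta)); w <- pmax(mu * (1 - mu), 1e-12)
      info <- t(xm * w) %*% xm + diag(1e-3, ncol(xm))
      se <- sqrt(diag(solve(info)))
      zv <- rf$coefficients / se
      cbind(Estimate = rf$coefficients, `Std. Error` = se, `z value` = zv,
            `Pr(>|z|)` = 2 * stats::pnorm(-abs(zv)))
    }
    cf[-1, , drop = FALSE]  # drop intercept
  }
  repeat {
    cf <- wald(current)
    if (is.null(cf)) break
    p <- cf[, "Pr(>|z|)"]
    if (all(p < alpha)) break
    worst <- current[which.max(p)]
    dropped <- c(dropped, worst)
    current <- setdiff(current, worst)
  }
  cf <- wald(current)
  or_table <- if (is.null(cf)) {
    data.frame(predictor = character(0), odds_ratio = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0),
               p_value = numeric(0))
  } else {
    z <- stats::qnorm(0.975)
    data.frame(predictor = current,
               odds_ratio = exp(cf[, "Estimate"]),
               ci_low = exp(cf[, "Estimate"] - z * cf[, "Std. Error"]),
               ci_high = exp(cf[, "Estimate"] + z * cf[, "Std. Error"]),
               p_value = cf[, "Pr(>|z|)"], row.names = NULL)
  }
  structure(list(retained = current, dropped = dropped,
                 coefficients = if (is.null(cf)) NULL else cf,
                 or_table = or_table, alpha = alpha),
            class = "stepwise_logistic")
}

#' @export
print.stepwise_logistic <- function(x, ...) {
  cat(sprintf("<stepwise_logistic> retained %d of %d predictors (alpha = %g)\n",
              length(x$retained), length(x$retained) + length(x$dropped),
              x$alpha))
  if (nrow(x$or_table) > 0) print(x$or_table, row.names = FALSE)
  invisible(x)
}

#' Marker-to-denominator expression-ratio comparison
#'
#' For each marker, per-core ratios marker/denominator are formed (cores with
#' denominator <= 0 are skipped with a warning) and averaged per patient —
#' ratio-then-mean over the replicate cores. Group means of the per-patient
#' ratios are compared between NR and R via Welch's t-test, and the group
#' means are z-scored across markers.
#'
#' @param table a `pathology_table` carrying per-core values.
#' @param denominator_marker marker id used as the denominator.
#' @param compartment "tumor" or "stroma".
#' @return data.frame with one row per marker (the denominator excluded):
#'   `marker`, `mean_nr`, `mean_r`, `z_nr`, `z_r`, `p_value`, `n_used`.
#' @export
ratio_analysis <- function(table, denominator_marker,
                           compartment = c("tumor", "stroma")) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(table, "pathology_table"))
  if (is.null(table$cores))
    stop("per-core values are required for ratio analysis", call. = FALSE)
  cores <- table$cores[[compartment]]
  if (!denominator_marker %in% colnames(cores))
    stop(sprintf("denominator marker '%s' not present", denominator_marker),
         call. = FALSE)
  labels <- table$patients$label
  denom <- cores[, denominator_marker, , drop = TRUE]
  if (length(dim(denom)) < 2) denom <- matrix(denom, ncol = 1)
  bad <- denom <= 0
  if (any(bad))
    warning(sprintf("%d core value(s) with non-positive denominator skipped",
                    sum(bad)), call. = FALSE)
  denom[bad] <- NA_real_
  markers <- setdiff(colnames(cores), denominator_marker)
  rows <- lapply(markers, function(m) {
    num <- cores[, m, , drop = TRUE]
    if (length(dim(num)) < 2) num <- matrix(num, ncol = 1)
    ratio <- rowMeans(num / denom, na.rm = TRUE)  # ratio-then-mean per patient
    ok <- is.finite(ratio)
    r_nr <- ratio[ok & labels == 0L]; r_r <- ratio[ok & labels == 1L]
    p <- if (length(r_nr) > 1 && length(r_r) > 1 &&
             (stats::sd(r_nr) > 0 || stats::sd(r_r) > 0))
      tryCatch(stats::t.test(r_nr, r_r)$p.value, error = function(e) NA_real_)
    else NA_real_
    data.frame(marker = m, mean_nr = mean(r_nr), mean_r = mean(r_r),
               p_value = p, n_used = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  zs <- function(v) if (stats::sd(v) == 0) rep(0, length(v))
        else (v - mean(v)) / stats::sd(v)
  out$z_nr <- zs(out$mean_nr)
  out$z_r <- zs(out$mean_r)
  out[, c("marker", "mean_nr", "mean_r", "z_nr", "z_r", "p_value", "n_used")]
}

#' Kaplan-Meier product-limit curve
#'
#' Product-limit estimator under right censoring (events precede censorings
#' at tied times, the standard convention); computed via
#' [survival::survfit()].
#'
#' @param time positive event/censoring times.
#' @param event event indicator (1 = event, 0 = censored).
#' @return a `km_curve`: list with `time` (ordered distinct times), `surv`,
#'   `n_risk`, `n_event`.
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0L) stop("at least one record is required", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0))
    stop_field("time", "must be positive and finite")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d time points, final S(t) = %.3f\n",
              length(x$time), x$surv[length(x$surv)]))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected chi-square with 1 degree of freedom and
#' hypergeometric variance at each event time, via [survival::survdiff()].
#'
#' @param time positive event/censoring times.
#' @param event event indicator (1 = event, 0 = censored).
#' @param group two-level group assignment.
#' @return a `logrank_result`: `chi_square`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("exactly two non-empty groups are required", call. = FALSE)
  if (sum(event) < 1L) stop("at least one event is required", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  structure(list(chi_square = unname(sd$chisq), df = 1L,
                 p_value = stats::pchisq(unname(sd$chisq), df = 1,
                                         lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank chi-square %.3f (df = %d), p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Survival stratification by predicted NAC response
#'
#' Assigns every patient to the "response" or "nonresponse" predicted group
#' using a fitted panel model, then compares overall and progression-free
#' survival between the groups per cohort (and combined) with Kaplan-Meier
#' curves and log-rank tests. Patients with missing survival annotations are
#' excluded with a warning.
#'
#' @param fit an `nac_panel` from [search_best_panel()].
#' @param table a `pathology_table` with survival annotations.
#' @return a `stratification`: list with `groups` (named per-patient), and
#'   per cohort (+"combined") per endpoint ("os", "pfs") the `km` curves by
#'   group and the `logrank` result.
#' @export
stratify_predicted <- function(fit, table) {
  stopifnot(inherits(fit, "nac_panel"), inherits(table, "pathology_table"))
  groups <- predict(fit, table, type = "group")
  pat <- table$patients
  cohorts <- c(unique(pat$cohort), "combined")
  out <- list(groups = groups, comparisons = list())
  for (co in cohorts) {
    sel <- if (co == "combined") rep(TRUE, nrow(pat)) else pat$cohort == co
    for (ep in c("os", "pfs")) {
      tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
      ok <- sel & is.finite(pat[[tcol]]) & !is.na(pat[[ecol]])
      if (sum(ok) < sum(sel))
        warning(sprintf("%d patient(s) without %s annotation excluded",
                        sum(sel) - sum(ok), toupper(ep)), call. = FALSE)
      g <- groups[pat$patient_id[ok]]
      res <- list(km = lapply(split(which(ok), g), function(idx)
                    km_curve(pat[[tcol]][idx], pat[[ecol]][idx])),
                  logrank = if (length(unique(g)) == 2L)
                    logrank_test(pat[[tcol]][ok], pat[[ecol]][ok], g)
                  else NULL)
      out$comparisons[[paste(co, ep, sep = ".")]] <- res
    }
  }
  class(out) <- "stratification"
  out
}

#' @export
print.stratification <- function(x, ...) {
  cat("<stratification> predicted groups:",
      sprintf("response = %d, nonresponse = %d\n",
              sum(x$groups == "response"), sum(x$groups == "nonresponse")))
  for (nm in names(x$comparisons)) {
    lr <- x$comparisons[[nm]]$logrank
    cat(sprintf("  %-14s %s\n", nm,
                if (is.null(lr)) "single predicted group; no test"
                else sprintf("log-rank p = %.4g", lr$p_value)))
  }
  invisible(x)
}
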