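test_that("the heuristic cutoff maximizes the 2x2 chi-square", {
  # perfectly separated values: cutoff falls between the groups
  values <- c(1, 2, 3, 10, 11, 12)
  labels <- c(0, 0, 0, 1, 1, 1)
  hc <- heuristic_cutoff(values, labels)
  expect_equal(hc$cutoff, 6.5)
  expect_equal(hc$chi_square, 6)  # n * 1 for a perfect 3/3 split
  expect_equal(c(hc$table$a, hc$table$b, hc$table$c, hc$table$d),
               c(3, 0, 0, 3))
  # brute-force oracle over all candidate midpoints
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(30)
    l <- rbinom(30, 1, 0.5); l[1:2] <- c(0L, 1L)
    hc <- heuristic_cutoff(v, l)
    u <- sort(unique(v))
    cand <- (head(u, -1) + tail(u, -1)) / 2
    chis <- sapply(cand, function(ct) {
      tab <- table(factor(v >= ct, c(FALSE, TRUE)), factor(l, 0:1))
      out <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
      if (is.nan(out)) 0 else out
    })
    expect_equal(hc$chi_square, max(chis), tolerance = 1e-12)
    expect_equal(hc$cutoff, cand[which(chis >= max(chis) - 1e-12)[1]])
  }
  expect_error(heuristic_cutoff(rep(1, 5), c(0, 1, 0, 1, 0)), "identical")
})

test_that("cutoff selection is anti-conservative under the null", {
  # the selected-cutoff chi-square test rejects far above the nominal 5%
  set.seed(2)
  rejections <- vapply(1:300, function(i) {
    v <- rnorm(100)
    l <- sample(rep(c(0L, 1L), each = 50))
    hc <- heuristic_cutoff(v, l)
    pchisq(hc$chi_square, df = 1, lower.tail = FALSE) < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.15)
})

test_that("odds ratios follow the closed form with zero-cell handling", {
  or1 <- univariate_or(contingency_table(10, 5, 4, 20))
  expect_equal(or1$odds_ratio, 10)
  expect_false(or1$correction_applied)
  expect_true(or1$ci_low <= or1$odds_ratio && or1$odds_ratio <= or1$ci_high)
  sym <- univariate_or(contingency_table(6, 6, 6, 6))
  expect_equal(sym$odds_ratio, 1)
  expect_true(sym$ci_low < 1 && sym$ci_high > 1)
  zero <- univariate_or(contingency_table(5, 0, 3, 7))
  expect_true(zero$correction_applied)
  expect_true(is.finite(zero$odds_ratio))
  # transposed exposure gives the reciprocal OR (no zero cells)
  fwd <- univariate_or(contingency_table(8, 3, 5, 9))
  rev <- univariate_or(contingency_table(5, 9, 8, 3))
  expect_equal(fwd$odds_ratio * rev$odds_ratio, 1, tolerance = 1e-12)
})

test_that("backward stepwise keeps strong predictors and honors alpha = 1", {
  set.seed(3)
  n <- 91
  x <- matrix(rnorm(n * 5), ncol = 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  retained <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(n * 5), ncol = 5,
                dimnames = list(NULL, paste0("v", 1:5)))
    y <- rbinom(n, 1, plogis(2 * x[, 1]))
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    "v1" %in% suppressWarnings(
      backward_stepwise_logistic(x, y, alpha = 0.05))$retained
  }, logical(1))
  expect_gte(mean(retained), 0.95)
  y <- rbinom(n, 1, 0.5); y[1:2] <- c(0L, 1L)
  full <- suppressWarnings(backward_stepwise_logistic(x, y, alpha = 1))
  expect_setequal(full$retained, colnames(x))  # vacuous threshold: identity
  expect_length(full$dropped, 0L)
  # pure-noise predictors are mostly all removed
  empties <- vapply(1:20, function(s) {
    set.seed(s + 50)
    x <- matrix(rnorm(200 * 3), ncol = 3,
                dimnames = list(NULL, paste0("v", 1:3)))
    y <- rbinom(200, 1, 0.5)
    length(suppressWarnings(
      backward_stepwise_logistic(x, y, alpha = 0.05))$retained) == 0
  }, logical(1))
  expect_gte(mean(empties), 0.5)  # ~ (1 - alpha)^p with wide tolerance
})

test_that("ratio analysis cancels global scale and z-scores by construction", {
  sim <- tiny_pathology(n_patients = c(20, 16), n_markers = 6, seed = 4)
  tbl <- sim$table
  res <- ratio_analysis(tbl, "M003", compartment = "tumor")
  expect_setequal(res$marker, setdiff(colnames(tbl$tumor), "M003"))
  # global multiplicative rescaling leaves ratios unchanged
  tbl2 <- tbl
  tbl2$cores$tumor <- tbl2$cores$tumor * 7
  res2 <- ratio_analysis(tbl2, "M003", compartment = "tumor")
  expect_equal(res$mean_nr, res2$mean_nr, tolerance = 1e-12)
  expect_equal(res$p_value, res2$p_value, tolerance = 1e-12)
  # z-scored group means have mean 0, sd 1 across markers
  expect_equal(mean(res$z_nr), 0, tolerance = 1e-12)
  expect_equal(sd(res$z_nr), 1, tolerance = 1e-12)
  # a duplicated marker equal to the denominator gives ratios exactly 1
  tbl3 <- tbl
  tbl3$cores$tumor[, "M001", ] <- tbl3$cores$tumor[, "M003", ]
  res3 <- ratio_analysis(tbl3, "M003", compartment = "tumor")
  row <- res3[res3$marker == "M001", ]
  expect_equal(row$mean_nr, 1, tolerance = 1e-12)
  expect_equal(row$mean_r, 1, tolerance = 1e-12)
  expect_true(is.na(row$p_value))  # degenerate comparison flagged as missing
})

test_that("Kaplan-Meier matches hand-computed product-limit values", {
  # all events: empirical survival 2/3, 1/3, 0
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # censoring at t = 2: S(1) = 2/3, S(3) = (2/3) * (1 - 1/1) = 0
  km2 <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)
  # all censored: survival stays at 1
  km3 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  # with no censoring KM equals 1 - ECDF at event times
  set.seed(5)
  t <- rexp(40)
  km4 <- km_curve(t, rep(1, 40))
  expect_equal(km4$surv, 1 - ecdf(t)(km4$time), tolerance = 1e-12)
  expect_error(km_curve(numeric(0), numeric(0)), "at least one")
  expect_error(km_curve(c(1, -1), c(1, 1)), "time")
})

test_that("log-rank matches a hand O/E/V tabulation and is symmetric", {
  # worked 6-patient example, no ties, no censoring
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1, 6)
  group <- c("a", "b", "a", "b", "a", "b")
  # manual observed-minus-expected and hypergeometric variance
  o_minus_e <- 0; v <- 0
  for (t in time) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == "a")
    d <- sum(time == t)
    o <- sum(time == t & group == "a")
    e <- d * n1 / n
    o_minus_e <- o_minus_e + (o - e)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  manual_chi <- o_minus_e^2 / v
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chi_square, manual_chi, tolerance = 1e-12)
  expect_equal(lr$p_value, pchisq(manual_chi, 1, lower.tail = FALSE))
  # swapping group labels changes nothing
  lr_swap <- logrank_test(time, event, ifelse(group == "a", "b", "a"))
  expect_equal(lr$chi_square, lr_swap$chi_square, tolerance = 1e-12)
  # identical groups -> statistic 0, p 1 (duplicate every patient)
  lr0 <- logrank_test(rep(time, 2), rep(event, 2),
                      rep(c("a", "b"), each = 6))
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  expect_error(logrank_test(time, event, rep("a", 6)), "two")
  expect_error(logrank_test(time, rep(0, 6), group), "event")
})

test_that("log-rank has power against a true hazard ratio", {
  rejections <- vapply(1:100, function(s) {
    sim <- tiny_pathology(n_patients = c(200, 200), n_markers = 2,
                          n_predictive = 0, hazard_ratio = 2,
                          censor_rate = 0, seed = s)
    pat <- sim$table$patients
    logrank_test(pat$os_time, pat$os_event,
                 sim$ground_truth$latent_response)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
})

test_that("predicted-group stratification partitions patients", {
  sim <- tiny_pathology(n_patients = c(40, 30), n_markers = 6,
                        n_predictive = 2, hazard_ratio = 2.5,
                        censor_rate = 0.2, seed = 6)
  pools <- build_pools(sim$table, n_pools = 2, seed = 6)
  fit <- search_best_panel(sim$table, pools, sizes = 2:3, bases = "tree",
                           data_types = "standardized", seed = 6)
  st <- stratify_predicted(fit, sim$table)
  expect_length(st$groups, 70L)
  expect_equal(sum(st$groups == "response") + sum(st$groups == "nonresponse"),
               70L)
  expect_named(st$comparisons,
               c("NAC.os", "NAC.pfs", "PCT.os", "PCT.pfs",
                 "combined.os", "combined.pfs"))
  lr <- st$comparisons$combined.os$logrank
  expect_true(is.null(lr) || (lr$p_value >= 0 && lr$p_value <= 1))
})
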