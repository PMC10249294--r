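test_that("CHA2DS2-VASc component sums", {
  base <- list(age = 40, sex = "M", heart_failure = 0, hypertension = 0,
               diabetes = 0, stroke_tia = 0, vascular_disease = 0)
  expect_equal(chadsvasc_score(base), 0)
  expect_equal(chadsvasc_score(modifyList(base, list(
    age = 70, sex = "F", hypertension = 1, diabetes = 1))), 4)
  expect_equal(chadsvasc_score(modifyList(base, list(
    age = 80, stroke_tia = 1))), 4)
  expect_error(chadsvasc_score(base[-3]), "heart_failure")
})

test_that("chi-square on a 2x2 table is uncorrected and exact on ties", {
  cmp <- compare_groups(matrix(c(15, 33, 18, 71), 2, byrow = TRUE),
                        variable_kind = "categorical", variable = "sex")
  expect_equal(cmp$statistic, 2.0729, tolerance = 1e-4)
  expect_equal(round(cmp$p_value, 2), 0.15)

  same <- compare_groups(matrix(c(20, 30, 20, 30), 2, byrow = TRUE),
                         variable_kind = "categorical")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("test selection follows the normality and variance gates", {
  set.seed(71)
  g <- rep(c("a", "b"), each = 50)
  x <- c(rnorm(50, 0, 1), rnorm(50, 2, 1))
  cmp <- compare_groups(x, g, "continuous")
  expect_equal(cmp$test_used, "t")
  expect_lt(cmp$p_value, 0.001)

  xw <- c(rnorm(50, 0, 1), rnorm(50, 0, 6))  # unequal variances
  expect_equal(compare_groups(xw, g, "continuous")$test_used, "welch")

  xs <- c(rexp(50), rexp(50, 0.5))           # skewed: Shapiro rejects
  expect_equal(compare_groups(xs, g, "continuous")$test_used, "wilcoxon")

  xz <- c(rep(1, 50), rnorm(50, 2))          # zero-variance group
  expect_equal(compare_groups(xz, g, "continuous")$test_used, "wilcoxon")
})

test_that("small samples without ties use the exact rank-sum distribution", {
  # heavy outliers force the Shapiro gate to the rank-sum branch
  x1 <- c(1, 1.1, 1.2, 30, 1.4, 1.5, 1.6, 28)
  x2 <- c(5.9, 6.2, 7.8, 8.4, 6.6, 7.1, 6.9, 7.5)
  cmp <- compare_groups(c(x1, x2), rep(c("a", "b"), each = 8), "continuous")
  expect_equal(cmp$test_used, "wilcoxon")
  expect_equal(cmp$p_value, wilcox.test(x1, x2, exact = TRUE)$p.value)
})

test_that("logistic fit reproduces closed-form results", {
  f <- fit_logistic(c(rep(1, 4), rep(0, 6)))
  expect_equal(unname(f$coefficients[1]), log(4 / 6))
  expect_equal(f$loglik, 4 * log(0.4) + 6 * log(0.6))
  expect_equal(f$aic, -2 * f$loglik + 2)

  y <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))
  x <- c(rep(1, 15), rep(0, 15))
  f2 <- fit_logistic(y, data.frame(x = x))
  expect_equal(unname(f2$odds_ratios["x"]), 4)
  expect_equal(unname(f2$coefficients["x"]), log(4))
})

test_that("the AIC and odds-ratio identities hold on arbitrary fits", {
  set.seed(72)
  X <- data.frame(a = rnorm(200), b = rbinom(200, 1, 0.4))
  y <- rbinom(200, 1, plogis(-0.5 + X$a))
  f <- fit_logistic(y, X)
  expect_equal(f$aic, -2 * f$loglik + 2 * length(f$coefficients))
  expect_identical(f$odds_ratios, exp(f$coefficients))
})

test_that("separation and rank deficiency are hard errors", {
  y <- c(rep(0, 10), rep(1, 10))
  x <- c(rep(0, 10), rep(1, 10))
  expect_error(fit_logistic(y, data.frame(x = x)), "separation")
  set.seed(73)
  X <- data.frame(a = rnorm(50))
  X$b <- 2 * X$a
  expect_error(fit_logistic(rbinom(50, 1, 0.5), X), "rank deficient")
  expect_error(fit_logistic(rep(1, 20)), "both classes")
})

test_that("univariate screening isolates per-variable failures", {
  set.seed(74)
  df <- data.frame(poaf = rbinom(300, 1, 0.4), good = rnorm(300),
                   flat = rep(1, 300))
  out <- univariate_screen(df, c("good", "flat"))
  expect_false(out$failed[out$variable == "good"])
  expect_true(out$failed[out$variable == "flat"])
  expect_error(univariate_screen(data.frame(poaf = c(rep(1, 5), rep(0, 40)),
                                            x = rnorm(45)), "x"),
               "10 events")
})

test_that("stepwise search is deterministic and handles an empty scope", {
  set.seed(75)
  X <- as.data.frame(matrix(rnorm(500 * 4), 500))
  names(X) <- paste0("x", 1:4)
  y <- rbinom(500, 1, plogis(-0.5 + X$x1))
  a <- stepwise_aic(y, X, names(X))
  b <- stepwise_aic(y, X, names(X))
  expect_identical(a$selected, b$selected)
  expect_identical(a$fit$aic, b$fit$aic)
  expect_true("x1" %in% a$selected)

  none <- stepwise_aic(y, X, character(0))
  expect_length(none$selected, 0)
  expect_length(none$fit$coefficients, 1)
})

test_that("stepwise agrees with the reference stepAIC implementation", {
  skip_if_not_installed("MASS")
  set.seed(76)
  X <- as.data.frame(matrix(rnorm(400 * 6), 400))
  names(X) <- paste0("x", 1:6)
  y <- rbinom(400, 1, plogis(-0.3 + 0.8 * X$x1 - 0.6 * X$x3))
  ours <- stepwise_aic(y, X, names(X))
  df <- cbind(y = y, X)
  ref <- MASS::stepAIC(glm(y ~ ., binomial(), df), direction = "both",
                       trace = 0)
  ref_sel <- setdiff(names(coef(ref)), "(Intercept)")
  expect_setequal(ours$selected, ref_sel)
  expect_equal(ours$fit$aic, AIC(ref))
})

test_that("under the null the stepwise keep-rate follows the AIC penalty", {
  # a noise variable survives iff its deviance gain beats the penalty 2:
  # P(chisq_1 > 2) = 0.157, so P(intercept-only | 10 candidates) ~ 0.18
  set.seed(77)
  n0 <- 0
  for (i in 1:30) {
    X <- as.data.frame(matrix(rnorm(400 * 10), 400))
    names(X) <- paste0("x", 1:10)
    y <- rbinom(400, 1, 0.35)
    if (length(stepwise_aic(y, X, names(X))$selected) == 0) n0 <- n0 + 1
  }
  expect_gt(n0 / 30, 0.02)
  expect_lt(n0 / 30, 0.45)
})

test_that("ROC: trapezoid AUC equals pair concordance; extremes behave", {
  r <- roc_analysis(c(3, 1, 2, 1), c(1, 1, 0, 0))
  expect_equal(r$auc, 0.625)
  expect_equal(roc_analysis(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_error(roc_analysis(1:5, rep(1, 5)), "classes")

  set.seed(78)
  for (i in 1:40) {
    n <- sample(10:80, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(seq_len(8), n, replace = TRUE)  # heavy ties
    expect_equal(roc_analysis(s, y)$auc, concordance_auc(s, y),
                 tolerance = 1e-12)
    expect_equal(roc_analysis(s, y)$auc + roc_analysis(-s, y)$auc, 1,
                 tolerance = 1e-12)
  }
})

test_that("ROC AUC agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(79)
  y <- rbinom(100, 1, 0.4)
  s <- rnorm(100) + y
  expect_equal(roc_analysis(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("operating points: Youden optimum and the sensitivity floor", {
  y <- c(rep(1, 10), rep(0, 10))
  s <- c(10, 9, 8, 7, 6, 5.5, 5, 4.5, 4, 1, 6.2, 5.8, 3, 2.8, 2.6, 2.4, 2.2,
         2.0, 1.8, 1.6)
  r <- roc_analysis(s, y, sensitivity_floor = 0.95)
  expect_gte(r$sens_floor$sensitivity, 0.95)
  # the floor point has max specificity among thresholds meeting the floor
  ok <- r$curve$tpr >= 0.95
  expect_equal(r$sens_floor$specificity, max(1 - r$curve$fpr[ok]))
  # Youden maximises tpr - fpr
  expect_equal(r$youden$sensitivity - (1 - r$youden$specificity),
               max(r$curve$tpr - r$curve$fpr))
})

test_that("correlation table: identities, ordering, degenerate flags", {
  df <- data.frame(x = c(1, 2, 3, 4), y = c(-1, -2, -3, -4),
                   z = c(1, 1, 1, 1), w = c(4, 3, 1, 2))
  out <- correlation_matrix(df, pairs = rbind(c("x", "x"), c("x", "y"),
                                              c("x", "z"), c("x", "w")))
  expect_equal(out$r[out$var1 == "x" & out$var2 == "x"], 1)
  expect_equal(out$r[out$var2 == "y"], -1)
  expect_true(out$undefined[out$var2 == "z"])
  expect_false(is.unsorted(rev(abs(out$r[!out$undefined]))))
})

test_that("band-power/total-power correlations mirror the power split", {
  df <- simulate_cohort(cohort_params(n_patients = 1000, seed = 80))
  out <- correlation_matrix(df, pairs = rbind(c("power_vlf", "total_power"),
                                              c("power_hf", "total_power")))
  r_vlf <- out$r[out$var1 == "power_vlf"]
  r_hf <- out$r[out$var1 == "power_hf"]
  expect_gt(r_vlf, r_hf)   # VLF carries most prescribed variance
  expect_gt(r_vlf, 0.8)
})
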