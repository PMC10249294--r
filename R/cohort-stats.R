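#' CHA2DS2-VASc score
#'
#' Standard stroke-risk score: congestive heart failure 1, hypertension 1,
#' age >= 75 2 (65--74: 1), diabetes 1, prior stroke/TIA 2, vascular
#' disease 1, female sex 1.
#'
#' @param record A list or one-row data.frame with fields `age`, `sex`
#'   (`"F"`/`"M"`), and 0/1 flags `heart_failure`, `hypertension`,
#'   `diabetes`, `stroke_tia`, `vascular_disease`.
#' @return Integer score in 0..9.
#' @export
chadsvasc_score <- function(record) {
  need <- c("age", "sex", "heart_failure", "hypertension", "diabetes",
            "stroke_tia", "vascular_disease")
  for (f in need) {
    if (is.null(record[[f]]) || is.na(record[[f]])) {
      stop("missing covariate for CHA2DS2-VASc: ", f)
    }
  }
  age_pts <- if (record$age >= 75) 2L else if (record$age >= 65) 1L else 0L
  as.integer(record$heart_failure) + as.integer(record$hypertension) +
    age_pts + as.integer(record$diabetes) + 2L * as.integer(record$stroke_tia) +
    as.integer(record$vascular_disease) + as.integer(record$sex == "F")
}

#' Normality-driven two-group comparison
#'
#' Reproduces the deterministic test-selection rule of the cohort analysis.
#' Continuous variables: Shapiro–Wilk on each group at alpha = 0.05; if
#' either group is non-normal, the two-sample Wilcoxon rank-sum test is
#' used (exact enumeration when the combined n <= 20 without ties, else the
#' tie- and continuity-corrected normal approximation); otherwise an F-test
#' of equal variances at alpha = 0.05 selects between the pooled t-test and
#' the Welch t-test.  A zero-variance group bypasses the variance test and
#' falls back to Wilcoxon.  Categorical variables: Pearson chi-square
#' *without* continuity correction.
#'
#' @param values For `"continuous"`: numeric vector of observations.  For
#'   `"categorical"`: a contingency table/matrix (groups x categories).
#' @param groups Group labels parallel to `values` (continuous only).
#' @param variable_kind `"continuous"` or `"categorical"`.
#' @param variable Optional variable name carried into the result.
#' @param alpha Significance level of the normality and variance gates.
#' @return A one-row data.frame: `variable`, `test_used` (one of `"t"`,
#'   `"welch"`, `"wilcoxon"`, `"chi_square"`), `statistic`, `p_value`, plus
#'   per-group mean/sd summaries for continuous variables.
#' @export
compare_groups <- function(values, groups = NULL,
                           variable_kind = c("continuous", "categorical"),
                           variable = "", alpha = 0.05) {
  variable_kind <- match.arg(variable_kind)

  if (variable_kind == "categorical") {
    tab <- as.matrix(values)
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    # group summaries: proportion in the last category (binary covariates)
    prop <- if (ncol(tab) == 2) tab[, 2] / rowSums(tab) else rep(NA_real_, 2)
    return(data.frame(variable = variable, test_used = "chi_square",
                      statistic = unname(ht$statistic),
                      p_value = unname(ht$p.value),
                      mean_1 = prop[1], sd_1 = NA_real_, n_1 = sum(tab[1, ]),
                      mean_2 = prop[2], sd_2 = NA_real_, n_2 = sum(tab[2, ])))
  }

  stopifnot(length(values) == length(groups))
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.factor(as.character(groups[ok]))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  g1 <- values[groups == levels(groups)[1]]
  g2 <- values[groups == levels(groups)[2]]
  if (length(g1) < 2 || length(g2) < 2) stop("need >= 2 observations per group")

  normal_p <- function(x) {
    if (length(unique(x)) < 3) return(0)   # degenerate: treat as non-normal
    shapiro.test(x)$p.value
  }
  zero_var <- var(g1) == 0 || var(g2) == 0
  non_normal <- zero_var || normal_p(g1) < alpha || normal_p(g2) < alpha

  if (non_normal) {
    n <- length(g1) + length(g2)
    has_ties <- anyDuplicated(values) > 0
    ht <- suppressWarnings(
      wilcox.test(g1, g2, exact = (n <= 20 && !has_ties), correct = TRUE))
    test_used <- "wilcoxon"
  } else if (var.test(g1, g2)$p.value < alpha) {
    ht <- t.test(g1, g2, var.equal = FALSE)
    test_used <- "welch"
  } else {
    ht <- t.test(g1, g2, var.equal = TRUE)
    test_used <- "t"
  }
  data.frame(variable = variable, test_used = test_used,
             statistic = unname(ht$statistic), p_value = unname(ht$p.value),
             mean_1 = mean(g1), sd_1 = sd(g1), n_1 = length(g1),
             mean_2 = mean(g2), sd_2 = sd(g2), n_2 = length(g2))
}

#' Binary logistic regression fit
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, convergence 1e-8 on the deviance, at most 100 iterations) with
#' Wald z-tests, odds ratios and AIC.  Complete or quasi-separation —
#' detected as any |coefficient| above 15 on the final iterate, where
#' odds ratios exceed 3 million per unit and the likelihood surface is
#' flat — raises an error of class `hrv_separation_error`.  A
#' rank-deficient design is a hard error.
#'
#' @param outcome 0/1 vector with both classes present.
#' @param design Numeric matrix or data.frame of covariates (no intercept
#'   column; one is added).
#' @return A `logistic_fit`: list with `coefficients`, `odds_ratios`,
#'   `se`, `wald_z`, `wald_p`, `loglik`, `aic`, `n`, `converged`,
#'   `fitted`, and the underlying `glm` object.
#' @export
fit_logistic <- function(outcome, design = NULL) {
  outcome <- as.numeric(outcome)
  if (!all(outcome %in% c(0, 1))) stop("outcome must be 0/1")
  if (length(unique(outcome)) < 2) stop("outcome must contain both classes")
  if (is.null(design) || ncol(as.matrix(design)) == 0) {
    df <- data.frame(.y = outcome)
    form <- .y ~ 1
  } else {
    design <- as.data.frame(design)
    qrX <- qr(cbind(1, as.matrix(design)))
    if (qrX$rank < ncol(design) + 1) stop("design matrix is rank deficient")
    df <- cbind(data.frame(.y = outcome), design)
    form <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", names(design)),
                                                  collapse = " + ")))
  }
  fit <- suppressWarnings(glm(form, family = binomial(), data = df,
                              control = list(epsilon = 1e-8, maxit = 100)))
  cf <- coef(fit)
  if (any(abs(cf) > 15)) {
    stop(structure(class = c("hrv_separation_error", "error", "condition"),
                   list(message = "complete or quasi-separation detected",
                        call = sys.call())))
  }
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  z <- cf / se
  ll <- as.numeric(stats::logLik(fit))
  structure(list(coefficients = cf, odds_ratios = exp(cf), se = se,
                 wald_z = z, wald_p = 2 * pnorm(-abs(z)),
                 loglik = ll, aic = -2 * ll + 2 * length(cf),
                 n = length(outcome), converged = fit$converged,
                 fitted = unname(stats::fitted(fit)), glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, loglik = %.3f, AIC = %.3f%s\n", x$n,
              x$loglik, x$aic, if (x$converged) "" else " (not converged)"))
  print(data.frame(coef = x$coefficients, OR = x$odds_ratios,
                   p = x$wald_p))
  invisible(x)
}

#' Univariate logistic screening
#'
#' One single-predictor logistic fit per candidate variable; odds ratios
#' are per unit of the variable's native scale.  Variables reaching
#' p < `alpha` are flagged as candidates for the multivariate stage.  A
#' variable whose fit fails (separation, zero variance) is reported as
#' failed and screening continues.
#'
#' @param cohort Data.frame with the outcome column and candidates.
#' @param candidates Character vector of candidate column names.
#' @param outcome Name of the 0/1 outcome column.
#' @param alpha Significance threshold for candidate flagging.
#' @return A data.frame: `variable`, `odds_ratio`, `coefficient`, `p`,
#'   `significant`, `failed`.
#' @export
univariate_screen <- function(cohort, candidates, outcome = "poaf",
                              alpha = 0.05) {
  y <- cohort[[outcome]]
  if (sum(y == 1) < 10) stop("need at least 10 events for screening")
  rows <- lapply(candidates, function(v) {
    fit <- tryCatch(fit_logistic(y, cohort[, v, drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(variable = v, odds_ratio = NA_real_,
                        coefficient = NA_real_, p = NA_real_,
                        significant = FALSE, failed = TRUE))
    }
    data.frame(variable = v, odds_ratio = unname(fit$odds_ratios[2]),
               coefficient = unname(fit$coefficients[2]),
               p = unname(fit$wald_p[2]),
               significant = unname(fit$wald_p[2]) < alpha, failed = FALSE)
  })
  do.call(rbind, rows)
}

#' Stepwise model selection by AIC
#'
#' Greedy bidirectional stepwise logistic regression: at each step every
#' single-variable addition (from `candidates`) and deletion is evaluated
#' and the move with the lowest AIC is applied; the search stops when no
#' move lowers the AIC.  Ties are broken by lower AIC, then fewer
#' parameters, then the input variable order — the search is fully
#' deterministic.  A move whose fit separates is skipped (and recorded).
#'
#' @param outcome 0/1 outcome vector.
#' @param data Data.frame holding the candidate columns.
#' @param candidates Candidate variable names (the search scope).
#' @param start `"full"` starts from all candidates, `"null"` from the
#'   intercept-only model; or a character vector of starting variables.
#' @param direction `"both"`, `"forward"` or `"backward"`.
#' @return A list: `fit` (the selected [fit_logistic()] model), `selected`
#'   (variable names), `trace` (data.frame of moves), `skipped`
#'   (separating moves).
#' @export
stepwise_aic <- function(outcome, data, candidates, start = "full",
                         direction = c("both", "forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(all(candidates %in% names(data)))
  current <- if (identical(start, "full")) candidates
             else if (identical(start, "null")) character(0)
             else intersect(start, candidates)

  fit_set <- function(vars) {
    tryCatch(fit_logistic(outcome, data[, vars, drop = FALSE]),
             error = function(e) NULL)
  }
  cur_fit <- fit_set(current)
  if (is.null(cur_fit)) stop("starting model fails to fit (separation or rank deficiency)")

  trace <- data.frame(step = 0L, move = "<start>", aic = cur_fit$aic)
  skipped <- character(0)
  step_i <- 0L
  repeat {
    step_i <- step_i + 1L
    moves <- list()
    if (direction %in% c("both", "forward")) {
      for (v in setdiff(candidates, current)) {
        moves[[length(moves) + 1L]] <- list(kind = "+", var = v,
                                            vars = c(current, v))
      }
    }
    if (direction %in% c("both", "backward")) {
      for (v in current) {
        moves[[length(moves) + 1L]] <- list(kind = "-", var = v,
                                            vars = setdiff(current, v))
      }
    }
    if (!length(moves)) break
    best <- NULL
    for (mv in moves) {
      f <- fit_set(mv$vars)
      if (is.null(f)) {
        skipped <- c(skipped, paste0(mv$kind, mv$var))
        next
      }
      mv$fit <- f
      mv$aic <- f$aic
      mv$k <- length(f$coefficients)
      better <- is.null(best) ||
        mv$aic < best$aic - 1e-12 ||
        (abs(mv$aic - best$aic) <= 1e-12 && mv$k < best$k)
      if (better) best <- mv
    }
    if (is.null(best) || best$aic >= cur_fit$aic - 1e-12) break
    current <- best$vars
    cur_fit <- best$fit
    trace <- rbind(trace, data.frame(step = step_i,
                                     move = paste0(best$kind, best$var),
                                     aic = cur_fit$aic))
  }
  list(fit = cur_fit, selected = current, trace = trace, skipped = skipped)
}

#' ROC analysis
#'
#' Builds the ROC curve over all distinct score thresholds, computes the
#' AUC by the trapezoid rule (equal, by construction, to the tie-corrected
#' Mann–Whitney concordance: the probability that a random case outscores a
#' random control, ties counting one half), and reports two operating
#' points: the Youden-optimal threshold (maximising sensitivity +
#' specificity - 1) and the highest-specificity threshold subject to a
#' sensitivity floor.
#'
#' @param scores Numeric risk scores (higher = more case-like).
#' @param outcome 0/1 vector, both classes present.
#' @param sensitivity_floor Floor for the constrained operating point.
#' @return A `roc_result`: list with `auc`, `curve` (data.frame
#'   `threshold`, `fpr`, `tpr`), `youden` and `sens_floor` operating points
#'   (each `threshold`, `sensitivity`, `specificity`), and `n_pos`/`n_neg`.
#' @export
roc_analysis <- function(scores, outcome, sensitivity_floor = 0.95) {
  outcome <- as.numeric(outcome)
  if (length(unique(outcome)) < 2) stop("both classes required for ROC")
  stopifnot(length(scores) == length(outcome))
  pos <- scores[outcome == 1]
  neg <- scores[outcome == 0]
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)

  youden_i <- which.max(tpr - fpr)
  ok <- which(tpr >= sensitivity_floor)
  floor_i <- ok[which.max(1 - fpr[ok])]
  op <- function(i) list(threshold = thr[i], sensitivity = tpr[i],
                         specificity = 1 - fpr[i])
  structure(list(auc = auc,
                 curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 youden = op(youden_i), sens_floor = op(floor_i),
                 sensitivity_floor = sensitivity_floor,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d cases / %d controls)\n",
              x$auc, x$n_pos, x$n_neg))
  cat(sprintf("  Youden:        sens %.2f spec %.2f\n",
              x$youden$sensitivity, x$youden$specificity))
  cat(sprintf("  sens >= %.2f: sens %.2f spec %.2f\n", x$sensitivity_floor,
              x$sens_floor$sensitivity, x$sens_floor$specificity))
  invisible(x)
}

#' Mann–Whitney concordance AUC
#'
#' Direct pair-enumeration AUC: the fraction of (case, control) pairs where
#' the case scores higher, ties counting one half.  Identical to the
#' trapezoid AUC of [roc_analysis()]; exposed for cross-checking.
#'
#' @inheritParams roc_analysis
#' @return AUC in \code{[0, 1]}.
#' @export
concordance_auc <- function(scores, outcome) {
  outcome <- as.numeric(outcome)
  pos <- scores[outcome == 1]
  neg <- scores[outcome == 0]
  if (!length(pos) || !length(neg)) stop("both classes required")
  r <- rank(c(pos, neg))
  np <- as.numeric(length(pos))
  nn <- as.numeric(length(neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Pairwise Pearson correlations of cohort features
#'
#' Complete-case Pearson coefficients for the requested feature pairs,
#' sorted by absolute correlation, descending.  A zero-variance member
#' leaves that pair's coefficient `NA` (flagged in the `undefined` column).
#'
#' @param features Data.frame of per-patient features.
#' @param pairs Two-column matrix or data.frame of feature-name pairs; if
#'   omitted, all pairs of the supplied columns.
#' @return A data.frame `var1`, `var2`, `r`, `n`, `undefined`, sorted by
#'   `|r|` descending.
#' @export
correlation_matrix <- function(features, pairs = NULL) {
  if (is.null(pairs)) {
    nm <- names(features)
    pairs <- t(utils::combn(nm, 2))
  }
  pairs <- as.matrix(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- features[[pairs[i, 1]]]
    b <- features[[pairs[i, 2]]]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 3) stop("need >= 3 complete rows per pair")
    und <- var(a) == 0 || var(b) == 0
    data.frame(var1 = pairs[i, 1], var2 = pairs[i, 2],
               r = if (und) NA_real_ else cor(a, b),
               n = length(a), undefined = und)
  })
  out <- do.call(rbind, rows)
  out[order(-ifelse(is.na(out$r), -Inf, abs(out$r))), , drop = FALSE]
}
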