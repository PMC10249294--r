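#' Cohort simulation settings
#'
#' Generative settings for [simulate_cohort()].  Defaults emulate a
#' 137-patient pre-operative cardiac-surgery cohort with a ~35% PoAF rate:
#' covariate prevalences and continuous-covariate moments follow the
#' whole-cohort summaries of such a study population, the outcome follows a
#' logistic model on the clinical covariates, and the HRV feature block is
#' drawn per outcome group with attenuated variability in the PoAF group.
#'
#' `logit_coefficients` must contain an `"(Intercept)"` entry; the other
#' names refer to covariate columns.  When `intercept_auto = TRUE` the
#' intercept is re-centred so the expected event rate at the covariate
#' means equals `target_rate`.
#'
#' @param n_patients Number of patients (>= 2).
#' @param covariate_prevalence Named prevalences in \code{[0,1]} for the binary
#'   covariates.
#' @param age_mean,age_sd Age distribution, years.
#' @param cont_covariates Named list of `c(mean, sd)` for continuous
#'   clinical covariates.
#' @param logit_coefficients Named log-odds per unit for the outcome model.
#' @param target_rate Expected outcome prevalence used to auto-centre the
#'   intercept.
#' @param intercept_auto Recentre the intercept at the covariate means?
#' @param hrv_effect Named list of `c(mean_noaf, mean_af, sd)` per HRV
#'   feature; features `total_power` and `lf_hf` are derived from the band
#'   powers instead of drawn.
#' @param seed Integer seed.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_patients = 137,
                          covariate_prevalence = c(
                            female = 0.24, diabetes = 0.28, hypertension = 0.78,
                            heart_failure = 0.04, thyroid_disease = 0.09,
                            stroke_tia = 0.07, prior_mi = 0.36,
                            vascular_disease = 0.36, copd = 0.15,
                            beta_blockers = 0.79, cabg = 0.64),
                          age_mean = 65.4, age_sd = 10.2,
                          cont_covariates = list(
                            bmi = c(29.6, 4.9), ef_pct = c(55.4, 9.1),
                            lved_mm = c(51.3, 6.9), lad_mm = c(40.0, 5.6),
                            leukocytes = c(8.2, 3.2), na = c(138.8, 4.1),
                            crp = c(5.1, 12.3)),
                          logit_coefficients = c(
                            "(Intercept)" = 0, age = 0.05, diabetes = 0.45,
                            thyroid_disease = 0.9, copd = 0.6),
                          target_rate = 0.35,
                          intercept_auto = TRUE,
                          hrv_effect = default_hrv_effect(),
                          seed = 1L) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (any(covariate_prevalence < 0 | covariate_prevalence > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  if (!"(Intercept)" %in% names(logit_coefficients)) {
    stop("logit_coefficients must include an '(Intercept)' entry")
  }
  structure(list(n_patients = as.integer(n_patients),
                 covariate_prevalence = covariate_prevalence,
                 age_mean = age_mean, age_sd = age_sd,
                 cont_covariates = cont_covariates,
                 logit_coefficients = logit_coefficients,
                 target_rate = target_rate,
                 intercept_auto = isTRUE(intercept_auto),
                 hrv_effect = hrv_effect,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' Default HRV group-effect table for cohort simulation
#'
#' Per-feature `c(mean_noaf, mean_af, sd)` used by [simulate_cohort()].
#' The NoAF/AF means encode the attenuated-variability contrast the
#' analysis is designed to detect (lower pNN50, band powers, SD2, entropy
#' and correlation dimension, higher recurrence rate, in the PoAF group);
#' the common sd is the pooled group spread.
#'
#' @return Named list of length-3 numeric vectors.
#' @export
default_hrv_effect <- function() {
  list(
    mean_rr    = c(935, 920, 120),
    mean_hr    = c(66, 66, 8.7),
    rmssd      = c(26, 24.1, 10.4),
    nn50       = c(465, 295, 395),
    pnn50      = c(6.0, 3.8, 5.1),
    tinn       = c(174.3, 171.7, 84),
    peak_vlf   = c(0.0055, 0.0053, 0.0037),
    peak_lf    = c(0.043, 0.043, 0.0007),
    peak_hf    = c(0.219, 0.228, 0.062),
    power_vlf  = c(1861, 1524, 1128),
    power_lf   = c(494, 397, 420),
    power_hf   = c(216, 195, 202),
    sd1        = c(18.4, 17.04, 7.4),
    sd2        = c(67.21, 59.36, 21.7),
    sd1_sd2    = c(0.277, 0.288, 0.084),
    apen       = c(1.17, 1.11, 0.158),
    sampen     = c(1.19, 1.10, 0.23),
    d2         = c(1.52, 1.028, 0.81),
    rec        = c(44.2, 46.3, 4.8),
    guzik      = c(50.0, 49.9, 0.04),
    porta      = c(50.1, 50.6, 2.0),
    slope      = c(52.43, 52.87, 1.1)
  )
}

#' Simulate a patient cohort with a logistic outcome model
#'
#' Per patient: age is Normal, binary clinical covariates are Bernoulli at
#' their prevalences, continuous covariates Normal; the PoAF outcome is
#' Bernoulli with probability `plogis(b0 + sum(beta * x))` on the clinical
#' covariates; the HRV feature block is then drawn Normal with
#' outcome-group-specific means (`total_power` is the sum of the three band
#' powers and `lf_hf` their ratio, so the power identity and its
#' correlation structure are present in the simulated data).  A
#' CHA2DS2-VASc score is computed from the simulated covariates.
#'
#' A degenerate outcome draw (all 0 or all 1) is regenerated with an
#' incremented seed, up to 10 attempts.
#'
#' @param params A [cohort_params()] object.
#' @return A data.frame, one row per patient, with clinical covariates, HRV
#'   features, `chadsvasc`, the outcome `poaf` and the true linear
#'   predictor `lp` (for recovery tests).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  for (attempt in 0:9) {
    df <- simulate_cohort_once(params, params$seed + attempt)
    if (length(unique(df$poaf)) == 2L) return(df)
  }
  stop("degenerate outcome draw in 10 attempts; adjust the outcome model")
}

simulate_cohort_once <- function(params, seed) {
  with_seed(seed, {
    n <- params$n_patients
    df <- data.frame(id = sprintf("P%04d", seq_len(n)))
    df$age <- rnorm(n, params$age_mean, params$age_sd)
    for (v in names(params$covariate_prevalence)) {
      df[[v]] <- rbinom(n, 1, params$covariate_prevalence[[v]])
    }
    df$sex <- ifelse(df$female == 1, "F", "M")
    for (v in names(params$cont_covariates)) {
      ms <- params$cont_covariates[[v]]
      df[[v]] <- rnorm(n, ms[1], ms[2])
    }

    beta <- params$logit_coefficients
    b0 <- beta[["(Intercept)"]]
    covs <- setdiff(names(beta), "(Intercept)")
    missing <- setdiff(covs, names(df))
    if (length(missing)) stop("outcome model names unknown covariate: ", missing[1])
    if (params$intercept_auto) {
      mu <- vapply(covs, function(v) {
        if (v == "age") params$age_mean
        else if (v %in% names(params$covariate_prevalence)) {
          params$covariate_prevalence[[v]]
        } else params$cont_covariates[[v]][1]
      }, numeric(1))
      b0 <- stats::qlogis(params$target_rate) - sum(beta[covs] * mu)
    }
    lp <- rep(b0, n)
    for (v in covs) lp <- lp + beta[[v]] * df[[v]]
    df$lp <- lp
    df$poaf <- rbinom(n, 1, stats::plogis(lp))

    grp <- df$poaf + 1L  # 1 = NoAF mean, 2 = AF mean
    eff <- params$hrv_effect
    for (feat in setdiff(names(eff), c("total_power", "lf_hf"))) {
      e <- eff[[feat]]
      df[[feat]] <- rnorm(n, mean = c(e[1], e[2])[grp], sd = e[3])
    }
    # non-negativity of magnitudes the metric contracts guarantee
    for (feat in intersect(c("rmssd", "nn50", "pnn50", "tinn", "sd1", "sd2",
                             "apen", "sampen", "d2", "rec"), names(df))) {
      df[[feat]] <- pmax(df[[feat]], 0)
    }
    for (feat in intersect(c("power_vlf", "power_lf", "power_hf"), names(df))) {
      df[[feat]] <- pmax(df[[feat]], 1)
    }
    if (all(c("power_vlf", "power_lf", "power_hf") %in% names(df))) {
      df$total_power <- df$power_vlf + df$power_lf + df$power_hf
      df$lf_hf <- df$power_lf / df$power_hf
    }
    df$chadsvasc <- vapply(seq_len(n), function(i) chadsvasc_score(df[i, ]),
                           numeric(1))
    df
  })
}
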