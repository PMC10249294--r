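#' Analysis configuration
#'
#' All tunable constants of the pipeline in one round-trippable object.
#' Every default is the package's documented convention; no stage reads a
#' hidden constant.
#'
#' @param cleaning Beat-cleaning settings: `median_window` (beats),
#'   `threshold_frac`, `mode` (`"remove"`/`"interpolate"`),
#'   `max_removal_frac`.
#' @param segment Optional analysis window: `start_s`, `duration_s`, or
#'   `NULL` for the whole recording.
#' @param time_domain `bin_width` (ms) of the TINN histogram.
#' @param freq_domain `fs` (Hz), `detrend_lambda` (or `NULL`), `ar_order`,
#'   `n_freq`, `band_edges` (4 increasing Hz values).
#' @param nonlinear `entropy_m`, `entropy_r_frac`, `guzik_squared`,
#'   `embed_m`, `embed_tau`, `rec_threshold_frac`, `d2_n_radii`,
#'   `d2_max_points`.
#' @param stats `alpha`, `stepwise_direction`, `stepwise_start`,
#'   `sensitivity_floor`, `min_events` (multivariate refusal threshold),
#'   `collinear_r` (|r| above which one of a feature pair is dropped before
#'   the stepwise stage).
#' @param seed Integer seed used by any stochastic stage.
#' @param out_dir Output directory for written reports, or `NULL`.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(cleaning = list(median_window = 11,
                                            threshold_frac = 0.3,
                                            mode = "remove",
                                            max_removal_frac = 0.2),
                            segment = NULL,
                            time_domain = list(bin_width = 7.8125),
                            freq_domain = list(fs = 4, detrend_lambda = 500,
                                               ar_order = 32, n_freq = 1025,
                                               band_edges = c(0, 0.04, 0.15, 0.4)),
                            nonlinear = list(entropy_m = 2,
                                             entropy_r_frac = 0.2,
                                             guzik_squared = TRUE,
                                             embed_m = 10, embed_tau = 1,
                                             rec_threshold_frac = 1,
                                             d2_n_radii = 30,
                                             d2_max_points = 3000),
                            stats = list(alpha = 0.05,
                                         stepwise_direction = "both",
                                         stepwise_start = "full",
                                         sensitivity_floor = 0.95,
                                         min_events = 10,
                                         collinear_r = 0.999),
                            seed = 1L,
                            out_dir = NULL) {
  cfg <- list(cleaning = cleaning, segment = segment,
              time_domain = time_domain, freq_domain = freq_domain,
              nonlinear = nonlinear, stats = stats,
              seed = as.integer(seed), out_dir = out_dir)
  structure(cfg, class = "analysis_config")
}

#' Save / load an analysis configuration
#'
#' YAML round trip: `load_config(save_config(cfg, path))` reproduces `cfg`.
#'
#' @param cfg An [analysis_config()].
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` the
#'   configuration.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw[!vapply(raw, is.null, logical(1))])
}

band_list <- function(edges) {
  list(VLF = c(edges[1], edges[2]), LF = c(edges[2], edges[3]),
       HF = c(edges[3], edges[4]))
}

#' Analyse a single RR recording
#'
#' Runs read -> artifact filter -> (optional segment) -> all three metric
#' blocks, returning one combined feature row.  Deterministic for fixed
#' input and configuration.
#'
#' @param rr_path Path to an RR file ([read_rr_series()] formats), or an
#'   [rr_series()] directly.
#' @param config An [analysis_config()].
#' @return A one-row data.frame with the time-domain, frequency-domain and
#'   non-linear columns, plus `n_nn` and `removal_fraction`; the
#'   `cleaning_report` is attached as attribute `cleaning`.
#' @export
analyze_patient <- function(rr_path, config = analysis_config()) {
  rr <- if (inherits(rr_path, "rr_series")) rr_path else read_rr_series(rr_path)
  cl <- config$cleaning
  cleaned <- withCallingHandlers(
    filter_artifacts(rr, median_window = cl$median_window,
                     threshold_frac = cl$threshold_frac, mode = cl$mode,
                     max_removal_frac = cl$max_removal_frac),
    error = function(e) e)
  if (inherits(cleaned, "error")) {
    stop(sprintf("%s [while cleaning %s]", conditionMessage(cleaned),
                 rr$source_id))
  }
  nn <- cleaned$series
  if (!is.null(config$segment)) {
    nn <- select_segment(nn, config$segment$start_s, config$segment$duration_s)
  }
  td <- time_domain_metrics(nn, bin_width = config$time_domain$bin_width)
  fd <- freq_domain_metrics(nn, fs = config$freq_domain$fs,
                            detrend_lambda = config$freq_domain$detrend_lambda,
                            order = config$freq_domain$ar_order,
                            n_freq = config$freq_domain$n_freq,
                            bands = band_list(config$freq_domain$band_edges))
  nl <- do.call(nonlinear_metrics, c(list(nn), config$nonlinear))
  out <- cbind(td, fd, nl,
               data.frame(n_nn = length(nn_intervals(nn)),
                          removal_fraction = cleaned$report$removal_fraction))
  attr(out, "cleaning") <- cleaned$report
  out
}

# feature columns a cohort analysis treats as HRV metrics
hrv_feature_names <- function() {
  c("mean_rr", "mean_hr", "sdnn", "rmssd", "nn50", "pnn50", "tinn",
    "peak_vlf", "peak_lf", "peak_hf", "power_vlf", "power_lf", "power_hf",
    "total_power", "lf_hf", "sd1", "sd2", "sd1_sd2", "guzik", "porta",
    "slope", "apen", "sampen", "d2", "rec")
}

#' Analyse a patient cohort end-to-end
#'
#' Merges per-patient HRV features with clinical covariates and reproduces
#' the cohort statistical procedure: per-variable two-group comparisons
#' (normality-driven test selection), univariate logistic screening,
#' stepwise-AIC multivariate modelling on the screened candidates (one of
#' any deterministically collinear feature pair is dropped first), ROC
#' characterisation of the selected model, and the correlation table of the
#' model variables.
#'
#' With fewer than `config$stats$min_events` events the multivariate stage
#' is refused (with a message); comparisons and screening are still
#' produced.
#'
#' @param cohort A data.frame (or CSV path) with one row per patient
#'   containing the outcome column, clinical covariates and either
#'   pre-computed HRV feature columns or an `rr_file` column.
#' @param rr_dir Directory of RR files when features are to be computed.
#' @param config An [analysis_config()].
#' @param outcome Name of the 0/1 outcome column.
#' @return An `hrv_cohort_report`: list with `comparisons`, `univariate`,
#'   `model` (stepwise result or `NULL`), `roc` (or `NULL`),
#'   `correlations`, `summary` (character), `n`, `n_events`.  When
#'   `config$out_dir` is set the tables are also written there as CSV.
#' @export
analyze_cohort <- function(cohort, rr_dir = NULL, config = analysis_config(),
                           outcome = "poaf") {
  if (is.character(cohort)) cohort <- read.csv(cohort, stringsAsFactors = FALSE)
  if (!outcome %in% names(cohort)) stop("outcome column not found: ", outcome)
  y <- cohort[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1")

  if (!is.null(rr_dir)) {
    if (!"rr_file" %in% names(cohort)) stop("rr_dir given but no rr_file column")
    feats <- lapply(file.path(rr_dir, cohort$rr_file), analyze_patient,
                    config = config)
    feats <- do.call(rbind, feats)
    cohort <- cbind(cohort[setdiff(names(cohort), names(feats))], feats)
  }

  hrv_vars <- intersect(hrv_feature_names(), names(cohort))
  clin_cont <- intersect(c("age", "bmi", "ef_pct", "lved_mm", "lad_mm",
                           "leukocytes", "na", "crp", "chadsvasc"),
                         names(cohort))
  clin_bin <- intersect(c("female", "diabetes", "hypertension", "heart_failure",
                          "thyroid_disease", "stroke_tia", "prior_mi",
                          "vascular_disease", "copd", "beta_blockers", "cabg"),
                        names(cohort))

  comparisons <- do.call(rbind, c(
    lapply(c(clin_cont, hrv_vars), function(v) {
      compare_groups(cohort[[v]], y, "continuous", variable = v,
                     alpha = config$stats$alpha)
    }),
    lapply(clin_bin, function(v) {
      tab <- table(factor(y, levels = c(0, 1)),
                   factor(cohort[[v]], levels = c(0, 1)))
      cmp <- compare_groups(tab, variable_kind = "categorical", variable = v)
      cmp
    })))

  candidates <- c(clin_cont, clin_bin, hrv_vars)
  n_events <- sum(y == 1)
  model <- NULL; roc <- NULL; correlations <- NULL
  sel_note <- ""
  if (n_events < config$stats$min_events) {
    message("fewer than ", config$stats$min_events,
            " events: regression stages refused")
    sel_note <- "regression stages refused (too few events)"
    screen <- data.frame(variable = character(0), odds_ratio = numeric(0),
                         coefficient = numeric(0), p = numeric(0),
                         significant = logical(0), failed = logical(0))
  } else {
    screen <- univariate_screen(cohort, candidates, outcome = outcome,
                                alpha = config$stats$alpha)
    cand <- screen$variable[screen$significant & !screen$failed]
    cand <- drop_collinear(cohort, cand, config$stats$collinear_r)
    if (length(cand)) {
      model <- stepwise_aic(y, cohort, cand,
                            start = config$stats$stepwise_start,
                            direction = config$stats$stepwise_direction)
      roc <- roc_analysis(model$fit$fitted, y,
                          sensitivity_floor = config$stats$sensitivity_floor)
      if (length(model$selected) >= 2) {
        correlations <- correlation_matrix(
          cohort[, model$selected, drop = FALSE])
      }
      sel_note <- paste("selected:", paste(model$selected, collapse = ", "))
    } else {
      model <- list(fit = fit_logistic(y), selected = character(0))
      roc <- roc_analysis(model$fit$fitted, y,
                          sensitivity_floor = config$stats$sensitivity_floor)
      sel_note <- "no univariate candidates; intercept-only model"
    }
  }

  summary_txt <- c(
    sprintf("cohort: n = %d (%d events / %d non-events)", length(y), n_events,
            length(y) - n_events),
    sprintf("comparisons: %d variables (%s)", nrow(comparisons),
            paste(sprintf("%s=%d", names(table(comparisons$test_used)),
                          table(comparisons$test_used)), collapse = ", ")),
    sprintf("univariate: %d of %d candidates significant at alpha %.2f",
            sum(screen$significant, na.rm = TRUE), nrow(screen),
            config$stats$alpha),
    sel_note,
    if (!is.null(roc)) {
      sprintf("ROC: AUC %.3f; Youden sens %.2f spec %.2f; sens>=%.2f spec %.2f",
              roc$auc, roc$youden$sensitivity, roc$youden$specificity,
              config$stats$sensitivity_floor, roc$sens_floor$specificity)
    })

  out <- structure(list(comparisons = comparisons, univariate = screen,
                        model = model, roc = roc,
                        correlations = correlations,
                        summary = summary_txt, n = length(y),
                        n_events = n_events),
                   class = "hrv_cohort_report")
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

drop_collinear <- function(cohort, vars, r_max) {
  if (length(vars) < 2) return(vars)
  keep <- vars[1]
  for (v in vars[-1]) {
    r <- vapply(keep, function(k) {
      a <- cohort[[k]]; b <- cohort[[v]]
      if (var(a) == 0 || var(b) == 0) return(1)
      abs(cor(a, b))
    }, numeric(1))
    if (all(r < r_max)) keep <- c(keep, v)
  }
  keep
}

#' @export
print.hrv_cohort_report <- function(x, ...) {
  cat("<hrv_cohort_report>\n")
  cat(paste(" ", x$summary, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a cohort report bundle to disk
#'
#' Emits `comparisons.csv`, `univariate.csv`, `model.csv`,
#' `correlations.csv`, `roc_points.csv` and `summary.txt` under `dir`.
#'
#' @param report An `hrv_cohort_report` from [analyze_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "hrv_cohort_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
            row.names = FALSE)
  write.csv(report$univariate, file.path(dir, "univariate.csv"),
            row.names = FALSE)
  if (!is.null(report$model) && inherits(report$model$fit, "logistic_fit")) {
    f <- report$model$fit
    write.csv(data.frame(term = names(f$coefficients),
                         coefficient = unname(f$coefficients),
                         odds_ratio = unname(f$odds_ratios),
                         p = unname(f$wald_p)),
              file.path(dir, "model.csv"), row.names = FALSE)
  }
  if (!is.null(report$correlations)) {
    write.csv(report$correlations, file.path(dir, "correlations.csv"),
              row.names = FALSE)
  }
  if (!is.null(report$roc)) {
    write.csv(report$roc$curve, file.path(dir, "roc_points.csv"),
              row.names = FALSE)
  }
  writeLines(report$summary, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' Write an RR series as a plain-ms text file
#'
#' One interval per line, milliseconds — the package's canonical fixture
#' format.
#'
#' @param rr An [rr_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rr_series <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  writeLines(format(rr$intervals, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}
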