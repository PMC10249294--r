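# Shared in-code fixtures.

# beat-by-beat series whose tachogram follows rr(t) = mean + a*sin(2*pi*f*t)
sinusoid_rr <- function(mean_rr = 900, amp = 50, freq = 0.1, duration_s = 600) {
  t <- 0
  rr <- numeric(0)
  while (t < duration_s) {
    iv <- mean_rr + amp * sin(2 * pi * freq * t)
    rr <- c(rr, iv)
    t <- t + iv / 1000
  }
  rr_series(rr, source_id = "sinusoid")
}

# random-walk-ish irregular but physiological series
fuzz_rr <- function(n, mean_rr = 850, sd = 40) {
  pmin(pmax(rnorm(n, mean_rr, sd), 400), 1800)
}

write_tmp_rr <- function(rr, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, paste0(rr$source_id, ".txt"))
  write_rr_series(rr, path)
  path
}

# null cohort: clinical covariates only, outcome independent of everything
null_cohort <- function(n = 137, rate = 0.35, seed = 1) {
  p <- cohort_params(n_patients = n, target_rate = rate,
                     logit_coefficients = c("(Intercept)" = qlogis(rate)),
                     intercept_auto = FALSE, seed = seed)
  simulate_cohort(p)
}
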