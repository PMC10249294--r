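make_tach <- function(values, fs = 4) {
  structure(list(values = values, fs = fs,
                 duration_s = (length(values) - 1) / fs, t0_s = 0),
            class = "uniform_tachogram")
}

test_that("resampling preserves constants, polynomials and sine amplitude", {
  expect_true(all(resample_tachogram(rr_series(rep(900, 100)))$values == 900))

  # rr(t) linear in time: spline interpolation of collinear points is exact
  t <- 0; rr <- numeric(0)
  while (t < 200) {
    iv <- 800 + 0.5 * t
    rr <- c(rr, iv)
    t <- t + iv / 1000
  }
  tach <- resample_tachogram(rr_series(rr))
  grid <- seq(0, by = 0.25, length.out = length(tach$values))
  expect_equal(tach$values, 800 + 0.5 * grid, tolerance = 1e-8)

  rrs <- sinusoid_rr(mean_rr = 900, amp = 40, freq = 0.1, duration_s = 400)
  tach <- resample_tachogram(rrs)
  v <- tach$values - mean(tach$values)
  tt <- seq(0, by = 0.25, length.out = length(v))
  amp <- sqrt(sum(2 * v * sin(2 * pi * 0.1 * tt) / length(tt))^2 +
                sum(2 * v * cos(2 * pi * 0.1 * tt) / length(tt))^2)
  expect_equal(amp, 40, tolerance = 0.01)
})

test_that("too-short recordings are refused for spectral analysis", {
  expect_error(resample_tachogram(rr_series(rep(900, 50))), "60 s")
  expect_error(resample_tachogram(rr_series(rep(900, 3))), "at least 4")
})

test_that("smoothness-priors detrending: limits and frequency response", {
  tach <- make_tach(rep(5, 50))
  expect_equal(detrend_smoothness_priors(tach, 500)$values, rep(0, 50),
               tolerance = 1e-8)
  # lambda = 0: the trend equals the input, output identically zero
  tach2 <- make_tach(rnorm(50))
  expect_equal(detrend_smoothness_priors(tach2, 0)$values, rep(0, 50),
               tolerance = 1e-10)
  expect_error(detrend_smoothness_priors(tach2, -1), "lambda")

  # slow drift removed (>90% power), HF oscillation preserved (within 5%)
  t <- seq(0, 500, by = 0.25)
  drift <- 50 * sin(2 * pi * 0.002 * t)
  osc <- 20 * sin(2 * pi * 0.25 * t)
  out <- detrend_smoothness_priors(make_tach(drift + osc), 500)$values
  proj <- function(x, f) {
    (2 / length(t)) * c(sum(x * sin(2 * pi * f * t)),
                        sum(x * cos(2 * pi * f * t)))
  }
  drift_pow <- sum(proj(out, 0.002)^2) / 2
  osc_pow <- sum(proj(out, 0.25)^2) / 2
  expect_lt(drift_pow, 0.1 * 50^2 / 2)
  expect_equal(osc_pow, 20^2 / 2, tolerance = 0.05)
})

test_that("AR spectrum integrates to the sample variance (Parseval)", {
  set.seed(51)
  w <- rnorm(4096)
  p <- ar_psd(make_tach(w))
  integral <- sum(diff(p$freqs) * (head(p$density, -1) + tail(p$density, -1)) / 2)
  expect_equal(integral, var(w), tolerance = 0.02)
  expect_error(ar_psd(make_tach(rnorm(40)), order = 32), "order")
})

test_that("a spectral peak is located at the driving frequency", {
  set.seed(52)
  t <- seq(0, 300, by = 0.25)
  v <- 30 * sin(2 * pi * 0.1 * t) + rnorm(length(t), 0, 1)
  fd <- band_powers(ar_psd(make_tach(v)))
  expect_equal(fd$peak_lf, 0.1, tolerance = 2 / 1024)
})

test_that("band powers recover analytic sinusoid powers (a^2/2)", {
  set.seed(53)
  t <- seq(0, 600, by = 0.25)
  v <- 40 * sin(2 * pi * 0.1 * t) + 20 * sin(2 * pi * 0.25 * t) +
    rnorm(length(t), 0, 3)
  fd <- band_powers(ar_psd(make_tach(v)))
  expect_equal(fd$power_lf, 800, tolerance = 0.1)
  expect_equal(fd$power_hf, 200, tolerance = 0.1)
  expect_equal(fd$lf_hf, 4, tolerance = 0.1)
})

test_that("band powers are independent of the display grid", {
  rr <- simulate_rr_series(simulation_params(duration_s = 1800, seed = 54))
  tach <- resample_tachogram(rr)
  a <- band_powers(ar_psd(tach, n_freq = 1025))
  b <- band_powers(ar_psd(tach, n_freq = 2049))
  expect_equal(b$power_vlf, a$power_vlf, tolerance = 0.005)
  expect_equal(b$power_lf, a$power_lf, tolerance = 0.005)
  expect_equal(b$power_hf, a$power_hf, tolerance = 0.005)
})

test_that("total power is exactly the sum of the three bands", {
  rr <- simulate_rr_series(simulation_params(duration_s = 900, seed = 55))
  fd <- freq_domain_metrics(rr, detrend_lambda = NULL)
  expect_identical(fd$total_power, fd$power_vlf + fd$power_lf + fd$power_hf)
  # and matches the stationary signal variance closely
  tach <- resample_tachogram(rr)
  expect_equal(fd$total_power + 0 * fd$power_vlf, var(tach$values),
               tolerance = 0.05)
})

test_that("power concentrated below 0.04 Hz leaves LF/HF empty and flagged", {
  freqs <- seq(0, 2, length.out = 2001)
  dens <- ifelse(freqs < 0.04, 1000, 0)
  psd <- structure(list(freqs = freqs, density = dens, model_order = 0L,
                        method = "welch_oracle", fs = 4), class = "psd")
  fd <- band_powers(psd)
  expect_equal(fd$total_power, fd$power_vlf)
  expect_equal(fd$power_lf, 0)
  expect_equal(fd$power_hf, 0)
  expect_true(is.na(fd$lf_hf))
  expect_true(isTRUE(attr(fd, "lf_hf_undefined")))
})

test_that("AR and Welch band powers agree on simulator fixtures", {
  # expected band powers of the two estimators agree; single-seed scatter
  # mixes the estimation noise of both, so compare seed means
  est <- sapply(56:58, function(s) {
    rr <- simulate_rr_series(simulation_params(duration_s = 3600, seed = s))
    tach <- resample_tachogram(rr)
    ar <- band_powers(ar_psd(tach))
    we <- band_powers(welch_psd_oracle(tach))
    c(ar$power_vlf, ar$power_lf, ar$power_hf,
      we$power_vlf, we$power_lf, we$power_hf)
  })
  m <- rowMeans(est)
  expect_equal(m[1], m[4], tolerance = 0.15)
  expect_equal(m[2], m[5], tolerance = 0.15)
  expect_equal(m[3], m[6], tolerance = 0.15)
})
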