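#' Resample an RR series onto a uniform time grid
#'
#' Cubic-spline interpolation of the NN-interval value as a function of
#' beat onset time onto a uniform grid at `fs` Hz spanning the recording.
#' Uneven beat times must be resampled before any Fourier or AR spectral
#' analysis; 4 Hz comfortably covers the 0.4-Hz upper edge of the HF band.
#' The mean is retained (detrending is a separate step).
#'
#' @param nn An [rr_series()]; NN intervals and their onset times are used.
#' @param fs Sampling rate, Hz; must exceed 0.8 Hz (twice the HF upper edge).
#' @return A `uniform_tachogram`: list with `values` (ms), `fs` (Hz),
#'   `duration_s`, `t0_s`.
#' @export
resample_tachogram <- function(nn, fs = 4) {
  stopifnot(inherits(nn, "rr_series"))
  if (fs <= 2 * 0.4) stop("fs must exceed 0.8 Hz to cover the HF band")
  keep <- nn$labels %in% c("normal", "interpolated")
  x <- nn$intervals[keep]
  t <- onset_times(nn)[keep]
  if (length(x) < 4) stop("need at least 4 NN intervals")
  dur <- t[length(t)] - t[1]
  if (dur < 60) stop("recording shorter than 60 s: too short for spectral analysis")
  grid <- seq(t[1], t[length(t)], by = 1 / fs)
  f <- splinefun(t, x, method = "fmm")
  structure(list(values = f(grid), fs = fs, duration_s = dur, t0_s = t[1]),
            class = "uniform_tachogram")
}

#' @export
print.uniform_tachogram <- function(x, ...) {
  cat(sprintf("<uniform_tachogram> %d samples at %g Hz (%.1f s)\n",
              length(x$values), x$fs, x$duration_s))
  invisible(x)
}

#' Smoothness-priors detrending
#'
#' Removes the slow aperiodic trend of a uniformly sampled tachogram: the
#' trend is `(I + lambda^2 * t(D2) %*% D2)^{-1} x` with `D2` the
#' second-difference operator, and the output is `x - trend`.  Acting as a
#' time-varying high-pass filter, larger `lambda` pushes the cutoff towards
#' DC (lambda = 500 at 4 Hz attenuates fluctuations slower than roughly
#' 0.03 Hz); `lambda = 0` reproduces the input as trend, leaving zeros.
#'
#' @param x A `uniform_tachogram` from [resample_tachogram()].
#' @param lambda Smoothing parameter, unitless, >= 0.
#' @return A `uniform_tachogram` of the detrended values (near-zero mean).
#' @export
detrend_smoothness_priors <- function(x, lambda = 500) {
  stopifnot(inherits(x, "uniform_tachogram"))
  if (lambda < 0) stop("lambda must be >= 0")
  v <- x$values
  n <- length(v)
  if (n < 10) stop("need at least 10 samples to detrend")
  D2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                            rep(1, n - 2)))
  A <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(D2)
  trend <- as.numeric(Matrix::solve(A, v))
  out <- x
  out$values <- v - trend
  out
}

#' Autoregressive power spectral density (Burg)
#'
#' Fits an AR model of fixed order by Burg's method (minimising combined
#' forward and backward prediction error, the standard parametric estimator
#' for short HRV records) and evaluates the AR spectrum on a uniform
#' frequency grid over \code{[0, fs/2]}.  The density is rescaled so its
#' integral over \code{[0, fs/2]} equals the sample variance of the input
#' (Parseval normalisation), giving band powers in ms^2; the integral is
#' computed by adaptive quadrature split at the AR pole angles, so spectra
#' with near-line peaks (poles close to the unit circle) are integrated
#' correctly even when the peaks are far narrower than the display grid.
#'
#' @param x A `uniform_tachogram` (typically detrended).
#' @param order AR model order; must satisfy `order < length/2`.
#' @param n_freq Number of points of the display grid.
#' @return A `psd` object: list with `freqs` (Hz), `density` (ms^2/Hz),
#'   `model_order`, `method = "ar_burg"`, `fs`, plus the continuous
#'   spectrum `shape`, its normalisation `norm` and the pole-angle
#'   `peak_freqs` used by [band_powers()] for exact band integration.
#' @export
ar_psd <- function(x, order = 32, n_freq = 1025) {
  stopifnot(inherits(x, "uniform_tachogram"))
  v <- x$values
  if (order >= length(v) / 2) stop("AR order must be below half the series length")
  fit <- ar.burg(v, aic = FALSE, order.max = order, demean = TRUE)
  a <- fit$ar
  shape <- function(f) {
    # |1 - sum_k a_k e^{-2 pi i f k / fs}|^{-2}, vectorised over f
    ph <- outer(f / x$fs, seq_along(a), function(ff, k) -2 * pi * ff * k)
    as.numeric(1 / Mod(1 - (cos(ph) %*% a) - 1i * (sin(ph) %*% a))^2)
  }
  # peak frequencies from the pole angles: quadrature breakpoints, so that
  # near-line peaks (far narrower than any display grid) integrate exactly
  pk <- sort(unique(abs(Arg(polyroot(c(1, -a)))))) * x$fs / (2 * pi)
  pk <- pk[pk > 0 & pk < x$fs / 2]
  total <- piecewise_integral(shape, 0, x$fs / 2, pk)
  norm <- var(v) / total
  freqs <- seq(0, x$fs / 2, length.out = n_freq)
  structure(list(freqs = freqs, density = shape(freqs) * norm,
                 model_order = order, method = "ar_burg", fs = x$fs,
                 shape = shape, norm = norm, peak_freqs = pk),
            class = "psd")
}

# adaptive quadrature of fun over [lo, hi], split at the interior
# breakpoints (spectral peaks) so sharp maxima sit at interval endpoints
piecewise_integral <- function(fun, lo, hi, breaks) {
  cuts <- sort(unique(c(lo, breaks[breaks > lo & breaks < hi], hi)))
  s <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    s <- s + stats::integrate(fun, cuts[i], cuts[i + 1L],
                              subdivisions = 500L, rel.tol = 1e-9,
                              stop.on.error = FALSE)$value
  }
  s
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd> %s, order %d, %d points over [0, %g] Hz\n",
              x$method, x$model_order, length(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Spectral band powers and peak frequencies
#'
#' Integrates a PSD over the standard half-open bands VLF \code{[0, 0.04)},
#' LF \code{[0.04, 0.15)} and HF \code{[0.15, 0.4)} Hz by the trapezoid rule on
#' the cumulative integral (band edges interpolated), so no frequency is
#' double-counted and the total equals the sum of the three bands exactly.
#' Peak frequencies are the in-band argmax of the density.
#'
#' @param psd A `psd` from [ar_psd()] (or a Welch estimate with the same
#'   fields).
#' @param bands Named list of `c(lo, hi)` band edges, Hz.
#' @return A one-row data.frame: `peak_vlf`, `peak_lf`, `peak_hf` (Hz),
#'   `power_vlf`, `power_lf`, `power_hf`, `total_power` (ms^2), `lf_hf`
#'   (unitless; `NA` with a `lf_hf_undefined` attribute when HF power is 0).
#' @export
band_powers <- function(psd,
                        bands = list(VLF = c(0, 0.04), LF = c(0.04, 0.15),
                                     HF = c(0.15, 0.4))) {
  stopifnot(inherits(psd, "psd"))
  if (max(psd$freqs) < max(vapply(bands, max, numeric(1)))) {
    stop("PSD grid does not cover the requested bands")
  }
  if (!is.null(psd$shape)) {
    # AR spectrum: pole-aware adaptive quadrature (grid-independent)
    pw <- vapply(bands, function(b) {
      psd$norm * piecewise_integral(psd$shape, b[1], b[2], psd$peak_freqs)
    }, numeric(1))
  } else {
    cum <- cumtrapz(psd$freqs, psd$density)
    cum_at <- function(f) approxfun(psd$freqs, cum)(f)
    pw <- vapply(bands, function(b) cum_at(b[2]) - cum_at(b[1]), numeric(1))
  }
  pk <- vapply(bands, function(b) {
    cand <- psd$freqs[psd$freqs >= b[1] & psd$freqs < b[2]]
    if (!is.null(psd$peak_freqs)) {
      cand <- c(cand, psd$peak_freqs[psd$peak_freqs >= b[1] &
                                       psd$peak_freqs < b[2]])
    }
    dens <- if (!is.null(psd$shape)) psd$shape(cand) else
      approxfun(psd$freqs, psd$density)(cand)
    cand[which.max(dens)]
  }, numeric(1))
  total <- sum(pw)
  # undefined (not infinite) when HF carries no power; a spectrum with
  # negligible total power (constant recording) is equally degenerate
  lf_hf <- if (pw[["HF"]] > 0 && total > 1e-8) pw[["LF"]] / pw[["HF"]]
           else NA_real_
  out <- data.frame(peak_vlf = pk[["VLF"]], peak_lf = pk[["LF"]],
                    peak_hf = pk[["HF"]], power_vlf = pw[["VLF"]],
                    power_lf = pw[["LF"]], power_hf = pw[["HF"]],
                    total_power = total, lf_hf = lf_hf)
  if (is.na(lf_hf)) attr(out, "lf_hf_undefined") <- TRUE
  out
}

#' Frequency-domain HRV metrics
#'
#' Composes [resample_tachogram()], [detrend_smoothness_priors()],
#' [ar_psd()] and [band_powers()] with the package defaults.  Set
#' `detrend_lambda = NULL` to skip detrending (e.g. when quantifying
#' prescribed oscillatory content of stationary synthetic records, where
#' the high-pass would bias the VLF estimate).
#'
#' @param nn An [rr_series()].
#' @param fs Resampling rate, Hz.
#' @param detrend_lambda Smoothness-priors parameter or `NULL` to skip.
#' @param order AR model order.
#' @param n_freq Frequency grid size.
#' @param bands Band-edge list as in [band_powers()].
#' @return The one-row data.frame of [band_powers()].
#' @export
freq_domain_metrics <- function(nn, fs = 4, detrend_lambda = 500, order = 32,
                                n_freq = 1025,
                                bands = list(VLF = c(0, 0.04),
                                             LF = c(0.04, 0.15),
                                             HF = c(0.15, 0.4))) {
  tach <- resample_tachogram(nn, fs = fs)
  if (!is.null(detrend_lambda)) {
    tach <- detrend_smoothness_priors(tach, lambda = detrend_lambda)
  }
  band_powers(ar_psd(tach, order = order, n_freq = n_freq), bands = bands)
}
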