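#' Poincare-plot descriptors SD1, SD2
#'
#' The Poincare plot scatters each NN interval against the next:
#' `x_i = rr_i`, `y_i = rr_(i+1)`.  Rotating the cloud by -45 degrees,
#' `u = (x + y)/sqrt(2)`, `v = (y - x)/sqrt(2)`, SD1 is the sample standard
#' deviation of `v` (dispersion across the identity line, beat-to-beat
#' variability) and SD2 that of `u` (dispersion along it, long-term
#' variability).
#'
#' @param nn An [rr_series()] or numeric NN vector, ms.
#' @return A one-row data.frame `sd1`, `sd2` (ms) and `sd1_sd2` (`NA` when
#'   SD2 is 0).
#' @export
poincare_descriptors <- function(nn) {
  x <- nn_values(nn)
  n <- length(x)
  if (n < 3) stop("need at least 3 NN intervals")
  xi <- x[-n]
  yi <- x[-1]
  sd1 <- sample_sd((yi - xi) / sqrt(2))
  sd2 <- sample_sd((yi + xi) / sqrt(2))
  data.frame(sd1 = sd1, sd2 = sd2,
             sd1_sd2 = if (sd2 > 0) sd1 / sd2 else NA_real_)
}

#' Heart-rate-asymmetry indices (Guzik, Porta, Slope)
#'
#' All three indices apportion a quantity between Poincare points above the
#' identity line (decelerations, `y > x`) and below it (accelerations);
#' points exactly on the line are excluded throughout.  Porta: percentage
#' of points below the line.  Guzik: percentage of the summed squared
#' perpendicular distances `d_i = |y_i - x_i|/sqrt(2)` contributed by points
#' above the line (set `squared = FALSE` for first-power distances; the
#' squared form is the original published definition).  Slope: percentage
#' of the summed absolute phase-angle deviations from the 45-degree
#' diagonal, `theta_i = |45 - atan2(y_i, x_i) in degrees|`, contributed by
#' points above the line.
#'
#' @param nn An [rr_series()] or numeric NN vector, ms.
#' @param squared Use squared distances in the Guzik index?
#' @return A one-row data.frame `guzik`, `porta`, `slope`, each in percent.
#' @export
#' @examples
#' asymmetry_indices(c(800, 850, 820, 860))  # porta 33.33
asymmetry_indices <- function(nn, squared = TRUE) {
  x <- nn_values(nn)
  n <- length(x)
  if (n < 3) stop("need at least 3 NN intervals")
  xi <- x[-n]
  yi <- x[-1]
  off <- yi != xi
  if (sum(off) < 2) stop("all Poincare points on the identity line (constant series)")
  xi <- xi[off]
  yi <- yi[off]
  above <- yi > xi

  d <- abs(yi - xi) / sqrt(2)
  if (squared) d <- d^2
  theta <- abs(45 - atan2(yi, xi) * 180 / pi)

  data.frame(
    guzik = 100 * sum(d[above]) / sum(d),
    porta = 100 * sum(!above) / length(xi),
    slope = 100 * sum(theta[above]) / sum(theta)
  )
}

# default entropy tolerance: 0.2 * SDNN of the series under analysis
default_entropy_r <- function(x) 0.2 * sample_sd(x)

#' Approximate entropy (ApEn)
#'
#' Template-matching irregularity: templates of length `m` are compared
#' with the Chebyshev distance, matches counted as `d <= r` *including* the
#' self-match; `Phi(m)` is the mean log relative match count and
#' `ApEn = Phi(m) - Phi(m+1)` (nats).  Lower values indicate a more
#' regular, more predictable signal.
#'
#' @param nn An [rr_series()] or numeric NN vector, ms.
#' @param m Template length.
#' @param r Tolerance, ms; defaults to 0.2 x SDNN of the series.
#' @return ApEn in nats.
#' @export
approximate_entropy <- function(nn, m = 2, r = NULL) {
  x <- nn_values(nn)
  if (length(x) < m + 2) stop("need at least m + 2 intervals")
  if (is.null(r)) r <- default_entropy_r(x)
  if (r < 0) stop("tolerance r must be >= 0")
  cpp_apen(x, as.integer(m), r)
}

#' Sample entropy (SampEn)
#'
#' As [approximate_entropy()] but self-matches are excluded: over unordered
#' template pairs, `B` counts matches at length `m` and `A` at length
#' `m + 1`; `SampEn = -ln(A/B)` (nats).  Less dependent on series length
#' than ApEn.
#'
#' @inheritParams approximate_entropy
#' @return SampEn in nats, or `NA` (flagged via attribute `undefined`) when
#'   `A` or `B` is zero — the series is too short or the tolerance too
#'   tight for any (m+1)-matches.
#' @export
sample_entropy <- function(nn, m = 2, r = NULL) {
  x <- nn_values(nn)
  if (length(x) < m + 2) stop("need at least m + 2 intervals")
  if (is.null(r)) r <- default_entropy_r(x)
  if (r < 0) stop("tolerance r must be >= 0")
  ab <- cpp_sampen_counts(x, as.integer(m), r)
  if (ab[1] == 0 || ab[2] == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  -log(ab[1] / ab[2])
}

# delay-embed x in dimension m with lag tau, optionally striding down to at
# most max_points vectors (documented cap, keeps pair counts tractable)
embed_series <- function(x, m, tau, max_points = 3000L) {
  M <- length(x) - (m - 1) * tau
  if (M < 2) stop("series too short for this embedding")
  if (M > max_points) {
    stride <- ceiling(M / max_points)
    idx <- seq(1L, length(x), by = stride)
    x <- x[idx]
  }
  x
}

#' Correlation dimension (D2)
#'
#' Grassberger–Procaccia estimate of the attractor dimension of the
#' delay-embedded NN series (dimension `m`, lag `tau`): the correlation sum
#' `C(r)` is the fraction of distinct vector pairs closer than `r`
#' (Euclidean); D2 is the least-squares slope of `log C(r)` versus `log r`
#' over the middle third of `n_radii` log-spaced radii between the 1st and
#' 99th percentile of the pairwise distances, restricted to radii with
#' `0 < C(r) < 1`.  A proxy for the number of dynamic variables governing
#' the series.
#'
#' For long records the embedded vectors are strided down to at most
#' `max_points` before pair evaluation.
#'
#' @param nn An [rr_series()] or numeric NN vector, ms.
#' @param m Embedding dimension.
#' @param tau Embedding lag, beats.
#' @param n_radii Number of log-spaced radii.
#' @param max_points Cap on embedded vectors.
#' @return D2 estimate (unitless), or `NA` flagged `undefined` when fewer
#'   than 3 usable radii exist (e.g. a constant series).
#' @export
correlation_dimension <- function(nn, m = 10, tau = 1, n_radii = 30,
                                  max_points = 3000L) {
  x <- nn_values(nn)
  if (length(x) < m * tau + 50) stop("series too short for D2 at this embedding")
  x <- embed_series(x, m, tau, max_points)
  d <- cpp_embed_dists(x, as.integer(m), as.integer(tau))
  undefined <- function() {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    out
  }
  if (max(d) == 0) return(undefined())
  q <- quantile(d[d > 0], c(0.01, 0.99), names = FALSE)
  if (q[1] <= 0 || q[2] <= q[1]) return(undefined())
  radii <- exp(seq(log(q[1]), log(q[2]), length.out = n_radii))
  np <- length(d)
  cr <- vapply(radii, function(r) sum(d < r) / np, numeric(1))
  usable <- which(cr > 0 & cr < 1)
  if (length(usable) < 3) return(undefined())
  mid <- usable[seq(floor(length(usable) / 3) + 1,
                    ceiling(2 * length(usable) / 3))]
  if (length(mid) < 3) mid <- usable
  fit <- lm(log(cr[mid]) ~ log(radii[mid]))
  unname(coef(fit)[2])
}

#' Recurrence rate (REC)
#'
#' Percentage of distinct delay-embedded vector pairs (dimension `m`, lag
#' `tau`) whose Euclidean distance is at or below `threshold` — the density
#' of off-diagonal points of the recurrence plot.  The default threshold,
#' `sqrt(m)` times the SDNN of the series, scales with both the embedding
#' dimension and the signal amplitude.
#'
#' @param nn An [rr_series()] or numeric NN vector, ms.
#' @param m Embedding dimension.
#' @param tau Embedding lag, beats.
#' @param threshold Recurrence threshold, ms; ties (`d == threshold`) count
#'   as recurrent.
#' @return REC in percent.
#' @export
recurrence_rate <- function(nn, m = 10, tau = 1, threshold = NULL) {
  x <- nn_values(nn)
  if (length(x) < m * tau + 10) stop("series too short for REC at this embedding")
  if (is.null(threshold)) threshold <- sqrt(m) * sample_sd(x)
  M <- length(x) - (m - 1) * tau
  if (M < 2) stop("fewer than 2 embedded vectors")
  cnt <- cpp_recurrence_count(x, as.integer(m), as.integer(tau), threshold)
  100 * 2 * cnt / (M * (M - 1))
}

#' The full non-linear HRV battery
#'
#' Computes every non-linear metric from one series with shared defaults:
#' Poincare SD1/SD2 and their ratio, the three asymmetry indices, ApEn,
#' SampEn, correlation dimension and recurrence rate.
#'
#' @param nn An [rr_series()] or numeric NN vector, ms.
#' @param entropy_m Template length for ApEn/SampEn.
#' @param entropy_r_frac Entropy tolerance as a fraction of SDNN.
#' @param guzik_squared Squared distances in the Guzik index?
#' @param embed_m,embed_tau Embedding dimension and lag for D2 and REC.
#' @param rec_threshold_frac REC threshold as a multiple of `sqrt(embed_m)`
#'   x SDNN.
#' @param d2_n_radii Radii count for the D2 slope fit.
#' @param d2_max_points Embedded-vector cap for D2.
#' @return A one-row data.frame: `sd1`, `sd2`, `sd1_sd2`, `guzik`, `porta`,
#'   `slope`, `apen`, `sampen`, `d2`, `rec`.
#' @export
nonlinear_metrics <- function(nn, entropy_m = 2, entropy_r_frac = 0.2,
                              guzik_squared = TRUE, embed_m = 10,
                              embed_tau = 1, rec_threshold_frac = 1,
                              d2_n_radii = 30, d2_max_points = 3000L) {
  x <- nn_values(nn)
  sdnn <- sample_sd(x)
  r <- entropy_r_frac * sdnn
  pc <- poincare_descriptors(x)
  # a (near-)constant series has no off-diagonal Poincare points; the
  # battery reports the asymmetry block as undefined instead of failing
  asym <- tryCatch(asymmetry_indices(x, squared = guzik_squared),
                   error = function(e) data.frame(guzik = NA_real_,
                                                  porta = NA_real_,
                                                  slope = NA_real_))
  cbind(pc, asym,
        data.frame(
          apen = approximate_entropy(x, m = entropy_m, r = r),
          sampen = as.numeric(sample_entropy(x, m = entropy_m, r = r)),
          d2 = as.numeric(correlation_dimension(x, m = embed_m, tau = embed_tau,
                                                n_radii = d2_n_radii,
                                                max_points = d2_max_points)),
          rec = recurrence_rate(x, m = embed_m, tau = embed_tau,
                                threshold = rec_threshold_frac * sqrt(embed_m) * sdnn)
        ))
}
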