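#' Simulation settings for synthetic RR series
#'
#' Bundles the generative settings for [simulate_rr_series()]: a resting
#' mean RR interval, the target modulation power in each of the standard
#' spectral bands (VLF 0--0.04 Hz, LF 0.04--0.15 Hz, HF 0.15--0.4 Hz), the
#' recording duration, an ectopy rate and a seed.  The defaults emulate a
#' 2-hour supine resting recording of a pre-operative cardiac-surgery
#' patient without PoAF: mean RR 935 ms and band powers VLF 1800, LF 500,
#' HF 200 ms^2.
#'
#' @param mean_rr Mean RR interval, ms.
#' @param band_power Named numeric vector of target modulation power per
#'   band, ms^2; names must be `VLF`, `LF`, `HF`; values >= 0.
#' @param band_edges Band edges in Hz, increasing, length 4
#'   (`0, 0.04, 0.15, 0.4`).
#' @param duration_s Recording length, s.
#' @param ectopy_rate Premature-beat rate, events/min (used by
#'   [inject_ectopics()] when composing fixtures).
#' @param n_sinusoids Number of random-phase sinusoids per band.
#' @param seed Integer seed; the series is fully reproducible from it.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(mean_rr = 935,
                              band_power = c(VLF = 1800, LF = 500, HF = 200),
                              band_edges = c(0, 0.04, 0.15, 0.4),
                              duration_s = 7200,
                              ectopy_rate = 0,
                              n_sinusoids = 20,
                              seed = 1L) {
  stopifnot(length(band_edges) == 4, !is.unsorted(band_edges, strictly = TRUE))
  if (any(band_power < 0)) stop("band powers must be >= 0")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (!all(c("VLF", "LF", "HF") %in% names(band_power))) {
    stop("band_power must be named VLF, LF, HF")
  }
  structure(list(mean_rr = mean_rr, band_power = band_power,
                 band_edges = band_edges, duration_s = duration_s,
                 ectopy_rate = ectopy_rate, n_sinusoids = n_sinusoids,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate an RR-interval series with prescribed band powers
#'
#' Builds a heart-period modulation signal m(t) on a 4-Hz grid as a sum,
#' per spectral band, of `n_sinusoids` random-phase sinusoids with
#' frequencies drawn uniformly in the band and a common amplitude scaled so
#' the band's total power equals the prescription (a sinusoid of amplitude
#' a carries power a^2/2).  Beats are then placed iteratively,
#' `t[k+1] = t[k] + (mean_rr + m(t[k]))/1000`, until the requested duration;
#' the emitted intervals are `mean_rr + m(t[k])`.
#'
#' Frequencies are drawn no lower than `2/duration_s` so every component
#' completes at least two cycles inside the recording; without this floor
#' the realised variance of near-DC components is ill-defined at the
#' record length.  (In the VLF band this corresponds to the conventional
#' boundary with ultra-low-frequency power, which a 2-h recording cannot
#' resolve.)
#'
#' @param params A [simulation_params()] object.
#' @return An [rr_series()]; all labels `"normal"`.  Attribute
#'   `modulation_var` records the sample variance of the generated
#'   modulation on its grid (Parseval check).
#' @export
simulate_rr_series <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, {
    fs_grid <- 4
    tg <- seq(0, params$duration_s, by = 1 / fs_grid)
    m <- numeric(length(tg))
    edges <- params$band_edges
    bands <- list(VLF = edges[1:2], LF = edges[2:3], HF = edges[3:4])
    f_min <- 2 / params$duration_s
    for (b in names(bands)) {
      P <- params$band_power[[b]]
      if (P <= 0) next
      K <- params$n_sinusoids
      lo <- max(bands[[b]][1], f_min)
      hi <- bands[[b]][2]
      if (lo >= hi) stop("band ", b, " unresolvable at this duration")
      f <- runif(K, lo, hi)
      phi <- runif(K, 0, 2 * pi)
      a <- sqrt(2 * P / K)
      mb <- numeric(length(tg))
      for (k in seq_len(K)) mb <- mb + a * sin(2 * pi * f[k] * tg + phi[k])
      # rescale so the band's realised sample power equals the prescription
      # (random near-coincident frequencies otherwise leave several-percent
      # realisation error in the band variance)
      m <- m + mb * sqrt(P / var(mb))
    }
    if (params$mean_rr - max(abs(m)) <= 0) {
      stop("modulation exceeds mean RR: negative intervals are non-physical")
    }
    m_fun <- approxfun(tg, m, rule = 2)
    est_n <- ceiling(params$duration_s / (params$mean_rr / 1000) * 1.5) + 8L
    rr <- numeric(est_n)
    t <- 0
    k <- 0L
    while (t < params$duration_s) {
      iv <- params$mean_rr + m_fun(t)
      k <- k + 1L
      rr[k] <- iv
      t <- t + iv / 1000
    }
    out <- rr_series(rr[seq_len(k)], source_id = sprintf("sim-seed%d", params$seed))
    attr(out, "modulation_var") <- var(m)
    out
  })
}

#' Inject ectopic beats into an RR series
#'
#' Emulates premature beats with compensatory pauses: at Poisson-placed
#' positions, interval j is scaled by 0.6 (the premature coupling interval)
#' and interval j+1 by 1.4 (the pause); both beats are labelled
#' `"ectopic"`.  Events that would overlap a previous event (or fall on the
#' last interval) are skipped and counted.
#'
#' @param rr An [rr_series()].
#' @param rate_per_min Event rate, events per minute; >= 0.
#' @param seed Integer seed for the Poisson placement.
#' @return A list with `series` (the modified [rr_series()]), `positions`
#'   (integer indices of all modified intervals) and `n_skipped`
#'   (overlapping events dropped).
#' @export
inject_ectopics <- function(rr, rate_per_min, seed = 1L) {
  stopifnot(inherits(rr, "rr_series"))
  if (rate_per_min < 0) stop("rate_per_min must be >= 0")
  n <- length(rr$intervals)
  if (rate_per_min == 0 || n < 2) {
    return(list(series = rr, positions = integer(0), n_skipped = 0L))
  }
  with_seed(seed, {
    dur_min <- sum(rr$intervals) / 60000
    n_ev <- rpois(1, rate_per_min * dur_min)
    x <- rr$intervals
    lab <- rr$labels
    used <- logical(n)
    positions <- integer(0)
    n_skipped <- 0L
    if (n_ev > 0) {
      j_all <- sort(sample.int(n - 1L, size = min(n_ev, n - 1L), replace = FALSE))
      if (n_ev > n - 1L) n_skipped <- n_ev - (n - 1L)
      for (j in j_all) {
        if (used[j] || used[j + 1L]) {
          n_skipped <- n_skipped + 1L
          next
        }
        x[j] <- 0.6 * x[j]
        x[j + 1L] <- 1.4 * x[j + 1L]
        lab[c(j, j + 1L)] <- "ectopic"
        used[c(j, j + 1L)] <- TRUE
        positions <- c(positions, j, j + 1L)
      }
    }
    list(series = rr_series(x, lab, rr$source_id),
         positions = positions, n_skipped = n_skipped)
  })
}
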