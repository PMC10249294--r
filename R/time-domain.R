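#' Time-domain HRV metrics
#'
#' Computes the standard time-domain battery from the normal-to-normal (NN)
#' intervals of a cleaned series: mean RR, mean heart rate, SDNN, RMSSD,
#' NN50/pNN50 and TINN.
#'
#' Conventions: mean HR is the mean of the instantaneous rates
#' `60000/rr` (not `60000/mean(rr)`); SDNN and every other standard
#' deviation in this package uses the sample (n-1) denominator; NN50 counts
#' successive differences strictly greater than 50 ms.
#'
#' @param nn An [rr_series()]; metrics use its NN intervals.
#' @param bin_width Histogram bin width for TINN, ms.
#' @return A one-row data.frame with columns `mean_rr`, `mean_hr`, `sdnn`,
#'   `rmssd`, `nn50`, `pnn50`, `tinn`.
#' @export
#' @examples
#' rr <- rr_series(c(800, 860, 900, 940, 1000))
#' time_domain_metrics(rr)
time_domain_metrics <- function(nn, bin_width = 7.8125) {
  x <- nn_values(nn)
  n <- length(x)
  if (n < 3) stop("need at least 3 NN intervals")
  d <- diff(x)
  nn50 <- sum(abs(d) > 50)
  data.frame(
    mean_rr = mean(x),
    mean_hr = mean(60000 / x),
    sdnn = sample_sd(x),
    rmssd = sqrt(mean(d^2)),
    nn50 = nn50,
    pnn50 = 100 * nn50 / (n - 1),
    tinn = tinn(nn, bin_width = bin_width)
  )
}

# accept either an rr_series or a bare numeric vector of NN intervals
nn_values <- function(nn) {
  if (inherits(nn, "rr_series")) nn_intervals(nn) else as.numeric(nn)
}

#' NN-interval histogram
#'
#' Histogram over contiguous half-open bins `[lo, hi)` of width `bin_width`
#' aligned to multiples of `bin_width` from 0.  The default width,
#' 1/128 s = 7.8125 ms, is the conventional TINN discretisation.
#'
#' @param nn An [rr_series()] or numeric NN vector, ms.
#' @param bin_width Bin width, ms; must be positive.
#' @return A list with `edges` (length nbins+1), `centers`, `counts`
#'   (summing to the series length) and `bin_width`.
#' @export
nn_histogram <- function(nn, bin_width = 7.8125) {
  if (bin_width <= 0) stop("bin_width must be positive")
  x <- nn_values(nn)
  if (length(x) < 3) stop("need at least 3 NN intervals")
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- (floor(max(x) / bin_width) + 1) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  idx <- findInterval(x, edges)            # half-open [edge_i, edge_{i+1})
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  list(edges = edges, centers = edges[-length(edges)] + bin_width / 2,
       counts = counts, bin_width = bin_width)
}

#' Triangular interpolation of the NN histogram (TINN)
#'
#' Fits a triangle to the NN-interval histogram: the apex is fixed at the
#' modal bin (centre X, height Y); the baseline endpoints N < X and M > X
#' are chosen on the bin-centre grid to minimise the squared difference
#' between the triangle and the histogram over all bins.  TINN = M - N, ms.
#'
#' Because the squared error decomposes into a left part depending only on
#' N and a right part depending only on M, the two endpoints are optimised
#' independently; a brute-force search over all (N, M) pairs gives the same
#' optimum.  The candidate grid is padded with empty bins on both flanks so
#' baselines extending beyond the observed range are penalised correctly.
#' A single-bin histogram returns `bin_width` by convention.  Modal ties
#' resolve to the lowest bin centre.
#'
#' @param nn An [rr_series()] or numeric NN vector, ms.
#' @param bin_width Bin width, ms.
#' @return TINN in ms.
#' @export
tinn <- function(nn, bin_width = 7.8125) {
  h <- if (is.list(nn) && all(c("centers", "counts") %in% names(nn))) nn
       else nn_histogram(nn, bin_width = bin_width)
  tinn_from_histogram(h)
}

tinn_from_histogram <- function(h) {
  nz <- which(h$counts > 0)
  if (length(nz) == 0L) stop("empty histogram")
  if (length(nz) == 1L) return(h$bin_width)

  w <- h$bin_width
  pad <- max(length(h$counts), 2L)
  centers <- c(h$centers[1] - rev(seq_len(pad)) * w, h$centers,
               h$centers[length(h$centers)] + seq_len(pad) * w)
  counts <- c(rep(0, pad), h$counts, rep(0, pad))

  apex <- which.max(counts)        # ties: lowest centre
  X <- centers[apex]
  Y <- counts[apex]

  # left flank: for candidate N at index iN < apex, bins left of N keep
  # their counts as error, bins in (N, X) are compared with the rising edge
  left_sse <- function(iN) {
    N <- centers[iN]
    e <- 0
    if (iN > 1) e <- e + sum(counts[seq_len(iN - 1)]^2)
    if (iN <= apex - 1) {
      i <- iN:(apex - 1)
      tri <- Y * (centers[i] - N) / (X - N)
      e <- e + sum((counts[i] - tri)^2)
    }
    e
  }
  right_sse <- function(iM) {
    M <- centers[iM]
    e <- 0
    if (iM < length(counts)) e <- e + sum(counts[(iM + 1):length(counts)]^2)
    if (iM >= apex + 1) {
      i <- (apex + 1):iM
      tri <- Y * (M - centers[i]) / (M - X)
      e <- e + sum((counts[i] - tri)^2)
    }
    e
  }
  cand_N <- seq_len(apex - 1L)
  cand_M <- (apex + 1L):length(counts)
  iN <- cand_N[which.min(vapply(cand_N, left_sse, numeric(1)))]
  iM <- cand_M[which.min(vapply(cand_M, right_sse, numeric(1)))]
  centers[iM] - centers[iN]
}
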