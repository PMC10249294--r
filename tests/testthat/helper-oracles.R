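# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition by direct enumeration, sharing no code with
# the package implementations they check.

# Approximate entropy: direct template counting, self-matches included.
apen_oracle <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    N <- n - mm + 1
    acc <- 0
    for (i in seq_len(N)) {
      cnt <- 0
      for (j in seq_len(N)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) cnt <- cnt + 1
      }
      acc <- acc + log(cnt / N)
    }
    acc / N
  }
  phi(m) - phi(m + 1)
}

# Sample entropy: direct pair counting over i < j, templates from the
# first n - m starting positions; -log(A/B), NA when A or B is 0.
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  N <- n - m
  A <- 0; B <- 0
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) NA_real_ else -log(A / B)
}

# Recurrence rate: full recurrence-matrix count over delay embeddings,
# main diagonal excluded, ties (d == threshold) recurrent.
rec_oracle <- function(x, m, tau, threshold) {
  M <- length(x) - (m - 1) * tau
  emb <- sapply(seq_len(m), function(k) x[(1 + (k - 1) * tau):((k - 1) * tau + M)])
  cnt <- 0
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i != j && sqrt(sum((emb[i, ] - emb[j, ])^2)) <= threshold) {
        cnt <- cnt + 1
      }
    }
  }
  100 * cnt / (M * (M - 1))
}

# TINN: exhaustive O(bins^2) search over every (N, M) baseline pair on the
# same padded bin-centre grid the package uses (pad rule: one grid length
# of empty bins each side), evaluating the full triangle SSE directly.
tinn_oracle <- function(h) {
  nz <- which(h$counts > 0)
  if (length(nz) <= 1) return(h$bin_width)
  pad <- max(length(h$counts), 2L)
  w <- h$bin_width
  centers <- c(h$centers[1] - rev(seq_len(pad)) * w, h$centers,
               h$centers[length(h$centers)] + seq_len(pad) * w)
  counts <- c(rep(0, pad), h$counts, rep(0, pad))
  apex <- which.max(counts)
  X <- centers[apex]; Y <- counts[apex]
  best <- Inf; best_tinn <- NA_real_
  for (iN in seq_len(apex - 1)) {
    for (iM in (apex + 1):length(centers)) {
      tri <- numeric(length(centers))
      left <- seq_len(apex)
      right <- apex:length(centers)
      tri[left] <- pmax(0, Y * (centers[left] - centers[iN]) /
                          (X - centers[iN]))
      tri[right] <- pmax(0, Y * (centers[iM] - centers[right]) /
                           (centers[iM] - X))
      tri[centers < centers[iN] | centers > centers[iM]] <- 0
      tri[apex] <- Y
      sse <- sum((counts - tri)^2)
      if (sse < best - 1e-12) {
        best <- sse
        best_tinn <- centers[iM] - centers[iN]
      }
    }
  }
  best_tinn
}

# AUC: exhaustive case/control pair enumeration, ties worth one half.
auc_oracle <- function(scores, outcome) {
  pos <- scores[outcome == 1]
  neg <- scores[outcome == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Smoothed-periodogram (Welch-style) PSD oracle shaped like the package's
# psd object, normalised to the sample variance like ar_psd.
welch_psd_oracle <- function(tach, spans = 11) {
  sp <- stats::spec.pgram(stats::ts(tach$values, frequency = tach$fs),
                          spans = spans, taper = 0, detrend = TRUE,
                          plot = FALSE)
  freqs <- c(0, sp$freq)
  dens <- c(sp$spec[1], sp$spec)
  integral <- sum(diff(freqs) * (head(dens, -1) + tail(dens, -1)) / 2)
  dens <- dens * stats::var(tach$values) / integral
  structure(list(freqs = freqs, density = dens, model_order = 0L,
                 method = "welch_oracle", fs = tach$fs),
            class = "psd")
}
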