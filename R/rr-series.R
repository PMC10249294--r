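#' RR-interval series
#'
#' An `rr_series` holds an ordered sequence of inter-beat (RR) intervals in
#' milliseconds together with a per-interval beat annotation.  It is the
#' universal input of every HRV metric in this package; downstream metrics
#' operate on the normal-to-normal (NN) subset only (labels `"normal"` or
#' `"interpolated"`).
#'
#' Labels are one of `"normal"`, `"ectopic"`, `"artifact"`, `"interpolated"`.
#' Beat onset times (seconds) are derived: the k-th interval starts at the
#' cumulative sum of the preceding intervals.
#'
#' @param intervals Numeric vector of RR intervals, ms.  Every interval must
#'   be strictly positive and below 5000 ms (a longer gap is not a credible
#'   inter-beat interval and must be treated as an artifact upstream).
#' @param labels Character vector of per-interval annotations, recycled from
#'   `"normal"` if omitted.
#' @param source_id Free-text identifier carried through reports.
#' @return An object of class `rr_series` with fields `intervals`, `labels`,
#'   `source_id`.
#' @seealso [read_rr_series()], [filter_artifacts()], [select_segment()]
#' @export
#' @examples
#' rr <- rr_series(c(800, 820, 810))
#' onset_times(rr)
rr_series <- function(intervals, labels = NULL, source_id = "") {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L) stop("empty RR series")
  if (anyNA(intervals)) stop("RR intervals contain missing values")
  bad <- which(intervals <= 0 | intervals >= 5000)
  if (length(bad)) {
    stop(sprintf("non-physiological RR interval %.6g ms at position %d",
                 intervals[bad[1]], bad[1]))
  }
  if (is.null(labels)) labels <- rep("normal", length(intervals))
  labels <- as.character(labels)
  if (length(labels) != length(intervals)) {
    stop("labels and intervals must have the same length")
  }
  ok <- labels %in% c("normal", "ectopic", "artifact", "interpolated")
  if (!all(ok)) stop("unknown beat label: ", labels[which(!ok)[1]])
  structure(list(intervals = intervals, labels = labels,
                 source_id = as.character(source_id)[1]),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x$intervals)
  cat(sprintf("<rr_series> %d intervals, %.1f s%s\n", n,
              sum(x$intervals) / 1000,
              if (nzchar(x$source_id)) paste0(", source ", x$source_id) else ""))
  tab <- table(x$labels)
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Beat onset times of an RR series
#'
#' Onset time of interval k (seconds): the sum of intervals 1..k-1 divided
#' by 1000; the first interval starts at 0.
#'
#' @param rr An [rr_series()].
#' @return Numeric vector of onset times, s, strictly increasing.
#' @export
onset_times <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  c(0, cumsum(rr$intervals[-length(rr$intervals)])) / 1000
}

#' Extract the normal-to-normal intervals
#'
#' @param rr An [rr_series()].
#' @return Numeric vector of the intervals labelled `"normal"` or
#'   `"interpolated"`, ms.
#' @export
nn_intervals <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  rr$intervals[rr$labels %in% c("normal", "interpolated")]
}

#' Read an RR-interval series from disk
#'
#' Supports plain-text files with one interval per line (milliseconds or
#' seconds) and an annotated beat CSV with header `rr,label`.  Beat labels
#' `N`, `V`, `S`, `A`, `X` map to normal, ectopic, ectopic, artifact and
#' artifact respectively.  In `auto` mode a beat CSV is recognised by its
#' header, and plain values are interpreted as seconds (then converted to
#' ms) when their median is below 10.
#'
#' @param path Path to the file.
#' @param fmt One of `"auto"`, `"plain_ms"`, `"plain_s"`, `"beat_csv"`.
#' @return An [rr_series()] with `source_id` set to the file name.
#' @export
read_rr_series <- function(path, fmt = c("auto", "plain_ms", "plain_s", "beat_csv")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty RR file: ", path)

  is_csv <- grepl("rr", tolower(lines[1]), fixed = TRUE) &&
    grepl(",", lines[1], fixed = TRUE)
  if (fmt == "beat_csv" || (fmt == "auto" && is_csv)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if (!all(c("rr", "label") %in% names(df))) {
      stop("beat CSV must have header columns 'rr' and 'label': ", path)
    }
    vals <- suppressWarnings(as.numeric(df$rr))
    if (anyNA(vals)) {
      stop(sprintf("non-numeric rr value at data line %d in %s",
                   which(is.na(vals))[1], path))
    }
    map <- c(N = "normal", V = "ectopic", S = "ectopic",
             A = "artifact", X = "artifact")
    lab <- map[toupper(trimws(df$label))]
    if (anyNA(lab)) {
      stop(sprintf("unknown beat label '%s' in %s",
                   df$label[which(is.na(lab))[1]], path))
    }
    return(check_positive(vals, path, rr_series(pmax(vals, 1e-9), lab,
                                                source_id = basename(path))))
  }

  vals <- suppressWarnings(as.numeric(trimws(lines)))
  if (anyNA(vals)) {
    stop(sprintf("non-numeric token at line %d in %s", which(is.na(vals))[1], path))
  }
  if (fmt == "plain_s" || (fmt == "auto" && median(vals) < 10)) {
    vals <- vals * 1000
  }
  check_positive(vals, path, NULL)
  rr_series(vals, source_id = basename(path))
}

# shared validation error with line context
check_positive <- function(vals, path, pass) {
  bad <- which(vals <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive interval at line %d in %s", bad[1], path))
  }
  pass
}

#' Artifact and ectopy filtering of an RR series
#'
#' Deterministic surrogate for the visual beat-by-beat inspection used in
#' clinical HRV practice.  Interval i is flagged when it deviates from the
#' local median by more than `threshold_frac` times that median; the local
#' median is taken over a centred window of `median_window` beats, shrinking
#' symmetrically at the ends of the series.  Beats already annotated as
#' ectopic or artifact are always flagged.  Flagged intervals are either
#' removed or replaced by a cubic-spline interpolation over beat time and
#' relabelled `"interpolated"`.
#'
#' If more than `max_removal_frac` of the beats are flagged the recording is
#' rejected outright (`"recording too corrupted"`), mirroring the exclusion
#' of unusable recordings from a study cohort.
#'
#' @param rr An [rr_series()].
#' @param median_window Odd window width in beats for the running median.
#' @param threshold_frac Fractional deviation from the local median that
#'   flags a beat.
#' @param mode `"remove"` drops flagged beats; `"interpolate"` replaces them
#'   (series length preserved).
#' @param max_removal_frac Corruption gate on the flagged fraction.
#' @return A list with components `series` (the cleaned [rr_series()]) and
#'   `report`, a `cleaning_report` with fields `n_input`, `n_removed`,
#'   `n_interpolated`, `removal_fraction` and per-rule hit counts.
#' @export
filter_artifacts <- function(rr, median_window = 11, threshold_frac = 0.3,
                             mode = c("remove", "interpolate"),
                             max_removal_frac = 0.2) {
  mode <- match.arg(mode)
  stopifnot(inherits(rr, "rr_series"))
  if (median_window < 3 || median_window %% 2 == 0) {
    stop("median_window must be an odd integer >= 3")
  }
  n <- length(rr$intervals)
  if (n < median_window) stop("series shorter than the median window")

  x <- rr$intervals
  half <- (median_window - 1L) / 2L
  loc_med <- vapply(seq_len(n), function(i) {
    k <- min(i - 1L, n - i, half)   # symmetric shrink at the edges
    median(x[(i - k):(i + k)])
  }, numeric(1))
  dev_hit <- abs(x - loc_med) > threshold_frac * loc_med
  lab_hit <- rr$labels %in% c("ectopic", "artifact")
  flagged <- dev_hit | lab_hit

  frac <- sum(flagged) / n
  if (frac > max_removal_frac) {
    stop(sprintf("recording too corrupted: %.1f%% of beats flagged (limit %.0f%%)",
                 100 * frac, 100 * max_removal_frac))
  }

  rule_hits <- c(median_rule = sum(dev_hit & !lab_hit),
                 labelled_ectopic = sum(rr$labels == "ectopic"),
                 labelled_artifact = sum(rr$labels == "artifact"))

  if (mode == "remove") {
    out <- rr_series(x[!flagged], rr$labels[!flagged], rr$source_id)
    report <- cleaning_report(n, sum(flagged), 0L, rule_hits)
  } else {
    out_int <- x
    out_lab <- rr$labels
    if (any(flagged)) {
      t <- onset_times(rr)
      good <- !flagged
      if (sum(good) < 4) stop("too few clean beats to interpolate")
      f <- splinefun(t[good], x[good], method = "fmm")
      out_int[flagged] <- pmin(pmax(f(t[flagged]), 1), 4999)
      out_lab[flagged] <- "interpolated"
    }
    out <- rr_series(out_int, out_lab, rr$source_id)
    report <- cleaning_report(n, 0L, sum(flagged), rule_hits)
  }
  list(series = out, report = report)
}

cleaning_report <- function(n_input, n_removed, n_interpolated, rule_hits) {
  structure(list(n_input = as.integer(n_input),
                 n_removed = as.integer(n_removed),
                 n_interpolated = as.integer(n_interpolated),
                 removal_fraction = (n_removed + n_interpolated) / n_input,
                 rule_hits = rule_hits),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %d beats in, %d removed, %d interpolated (%.2f%%)\n",
              x$n_input, x$n_removed, x$n_interpolated, 100 * x$removal_fraction))
  cat("  rule hits:", paste(names(x$rule_hits), x$rule_hits, sep = "=",
                            collapse = " "), "\n")
  invisible(x)
}

#' Select a time window from an RR series
#'
#' Keeps the intervals whose onset time lies in
#' `[start_s, start_s + duration_s)`.
#'
#' @param rr An [rr_series()].
#' @param start_s Window start, seconds from the first beat.
#' @param duration_s Window length, seconds; must be positive.
#' @return An [rr_series()] restricted to the window, with attributes
#'   `window_start_s` and `window_duration_s`.
#' @export
select_segment <- function(rr, start_s, duration_s) {
  stopifnot(inherits(rr, "rr_series"))
  if (start_s < 0) stop("start_s must be >= 0")
  if (duration_s <= 0) stop("duration_s must be > 0")
  t <- onset_times(rr)
  keep <- t >= start_s & t < start_s + duration_s
  if (!any(keep)) stop("empty selection: window lies outside the recording")
  out <- rr_series(rr$intervals[keep], rr$labels[keep], rr$source_id)
  attr(out, "window_start_s") <- start_s
  attr(out, "window_duration_s") <- duration_s
  out
}
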