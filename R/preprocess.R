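#' Construct a PPG recording
#'
#' @param samples Numeric amplitude vector (a.u.), >= 2 samples.
#' @param fs Sampling rate, Hz (> 0).
#' @param subject_id,state Labels.
#' @param t0 Time of the first sample, seconds.
#' @param artifact_times Optional bookkeeping of injected artifact centres.
#' @return Object of class `ppg_recording`.
#' @export
ppg_recording <- function(samples, fs, subject_id = NA_character_,
                          state = NA_character_, t0 = 0,
                          artifact_times = numeric(0)) {
  if (!is.numeric(samples) || length(samples) < 2L) {
    stop("`samples` must be a numeric vector with at least 2 samples")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  structure(
    list(samples = as.numeric(samples), fs = fs, subject_id = subject_id,
         state = state, t0 = t0, artifact_times = artifact_times),
    class = "ppg_recording"
  )
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf("<ppg_recording> %s/%s: %.1f s at %g Hz (%d samples), t0 = %g s\n",
              x$subject_id, x$state, length(x$samples) / x$fs, x$fs,
              length(x$samples), x$t0))
  invisible(x)
}

#' @export
duration.ppg_recording <- function(x) length(x$samples) / x$fs

duration <- function(x) UseMethod("duration")

#' Preprocessing configuration
#'
#' Defaults follow the standard protocol for finger-PPG stress recordings:
#' discard the first and last 30 s (sensor settling), band-pass 0.5-3.0 Hz
#' (60-180 bpm pulse band), and remove beat intervals whose z-score magnitude
#' reaches `z_threshold` (T = 2).
#'
#' @param trim_head_s,trim_tail_s Seconds discarded at each end.
#' @param band_low,band_high Band-pass edges, Hz.
#' @param z_threshold Outlier z-score threshold T (> 0).
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(trim_head_s = 30, trim_tail_s = 30,
                              band_low = 0.5, band_high = 3.0,
                              z_threshold = 2) {
  stopifnot(trim_head_s >= 0, trim_tail_s >= 0,
            band_low > 0, band_high > band_low, z_threshold > 0)
  structure(
    list(trim_head_s = trim_head_s, trim_tail_s = trim_tail_s,
         band_low = band_low, band_high = band_high,
         z_threshold = z_threshold),
    class = "preprocess_config"
  )
}

#' Trim noisy head and tail off a recording
#'
#' @param rec A `ppg_recording`.
#' @param head_s,tail_s Seconds to discard from the start and end.
#' @return The trimmed `ppg_recording`, with `t0` advanced by `head_s`.
#' @export
trim_recording <- function(rec, head_s = 30, tail_s = 30) {
  stopifnot(inherits(rec, "ppg_recording"))
  n <- length(rec$samples)
  if (n / rec$fs <= head_s + tail_s) {
    stop("recording too short to trim: duration must exceed head_s + tail_s")
  }
  drop_head <- floor(head_s * rec$fs)
  drop_tail <- floor(tail_s * rec$fs)
  out <- rec
  out$samples <- rec$samples[(drop_head + 1L):(n - drop_tail)]
  out$t0 <- rec$t0 + head_s
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' A 4th-order Butterworth band-pass (two pole pairs per edge) applied
#' forward-backward with [signal::filtfilt()], so peak times are not skewed by
#' filter group delay. The signal is demeaned first; DC sits in the stopband
#' anyway, and removing it shrinks the filter's edge transients.
#'
#' @param rec A `ppg_recording`.
#' @param low,high Band edges, Hz; require `0 < low < high < fs/2`.
#' @return Filtered `ppg_recording`, same length and sampling rate.
#' @export
bandpass <- function(rec, low = 0.5, high = 3.0) {
  stopifnot(inherits(rec, "ppg_recording"))
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  x <- rec$samples - mean(rec$samples)
  n <- length(x)
  # odd-reflection padding keeps filtfilt's start-up transients out of the
  # data span (the 0.5 Hz edge has a multi-second impulse response)
  pad <- min(ceiling(10 * rec$fs), n - 1L)
  left <- 2 * x[1L] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(left, x, right)))
  out <- rec
  out$samples <- y[(pad + 1L):(pad + n)]
  out
}

# Prominence of each candidate local maximum, computed over candidates and the
# valleys between them (signal edges act as valleys).
peak_prominence <- function(x, pk) {
  m <- length(pk)
  h <- x[pk]
  # deepest point between consecutive candidate peaks
  valley <- numeric(m + 1L)
  valley[1L] <- min(x[seq_len(pk[1L])])
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      valley[i + 1L] <- min(x[pk[i]:pk[i + 1L]])
    }
  }
  valley[m + 1L] <- min(x[pk[m]:length(x)])
  prom <- numeric(m)
  for (j in seq_len(m)) {
    lmin <- valley[j]
    i <- j - 1L
    while (i >= 1L && h[i] <= h[j]) {
      lmin <- min(lmin, valley[i])
      i <- i - 1L
    }
    rmin <- valley[j + 1L]
    i <- j + 1L
    while (i <= m && h[i] <= h[j]) {
      rmin <- min(rmin, valley[i + 1L])
      i <- i + 1L
    }
    prom[j] <- h[j] - max(lmin, rmin)
  }
  prom
}

#' Detect systolic peaks and extract peak-to-peak intervals
#'
#' Local-maxima detection on the (filtered) waveform with a prominence
#' threshold of 0.3 x signal SD and a minimum inter-peak distance of `fs`/3
#' samples: the 3 Hz upper band edge of the pulse filter implies at most
#' 180 bpm, i.e. no two true beats closer than 1/3 s. When two candidates
#' violate the distance the higher one is kept.
#'
#' @param rec A (filtered) `ppg_recording` containing at least two beats.
#' @return A `ppi_series`: `peak_times` (s, on the recording's own time axis
#'   starting at 0), `intervals` (ms), and an all-`FALSE` `removal_mask`.
#' @export
detect_peaks <- function(rec) {
  stopifnot(inherits(rec, "ppg_recording"))
  x <- rec$samples
  n <- length(x)
  i <- 2:(n - 1L)
  cand <- i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
  if (length(cand) < 2L) stop("fewer than 2 peaks found in recording")
  prom <- peak_prominence(x, cand)
  keepable <- cand[prom >= 0.3 * stats::sd(x)]
  if (length(keepable) < 2L) stop("fewer than 2 peaks found in recording")
  min_dist <- rec$fs / 3
  ord <- keepable[order(x[keepable], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  }
  kept <- sort(kept)
  peak_times <- (kept - 1L) / rec$fs
  structure(
    list(peak_times = peak_times,
         intervals = diff(peak_times) * 1000,
         removal_mask = logical(length(kept) - 1L)),
    class = "ppi_series"
  )
}

#' @export
print.ppi_series <- function(x, ...) {
  cat(sprintf("<ppi_series> %d intervals, mean %.1f ms, %d flagged\n",
              length(x$intervals), mean(x$intervals), sum(x$removal_mask)))
  invisible(x)
}

#' Flag outlying peak-to-peak intervals by z-score
#'
#' A single, non-iterative pass: intervals with
#' \eqn{|x_i - \bar{x}| / s \ge T} are flagged, where \eqn{s} is the
#' population SD (denominator n) of all intervals in the trimmed recording.
#' If the intervals have zero spread the call is a no-op.
#'
#' @param ppi A `ppi_series` with >= 3 intervals.
#' @param T Threshold (default 2).
#' @return The `ppi_series` with `removal_mask` set; intervals untouched.
#' @export
remove_outlier_ppi <- function(ppi, T = 2) {
  stopifnot(inherits(ppi, "ppi_series"), T > 0)
  x <- ppi$intervals
  if (length(x) < 3L) stop("need at least 3 intervals to assess outliers")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) return(ppi)
  mask <- abs(x - mean(x)) / s >= T
  if (all(mask)) stop("degenerate input: every interval flagged as outlier")
  ppi$removal_mask <- mask
  ppi
}

#' Replace flagged intervals to obtain NN intervals
#'
#' Every flagged interval is replaced by the median of its nearest surviving
#' neighbours on either side (the median of two values being their mean); a
#' flagged run at a boundary copies its single nearest survivor. Runs of
#' consecutive flags all use the run's flanking survivors. Length is
#' preserved.
#'
#' @param ppi A `ppi_series` with `removal_mask` set.
#' @return An `nni_series`: `intervals` (ms), `replaced` flags, `times`
#'   (ending beat time of each interval, s), `start_time` (absolute time of
#'   the series origin, s) and `duration_s`.
#' @export
replace_removed <- function(ppi) {
  stopifnot(inherits(ppi, "ppi_series"))
  x <- ppi$intervals
  mask <- ppi$removal_mask
  if (all(mask)) stop("degenerate input: all intervals flagged")
  surv <- which(!mask)
  out <- x
  for (i in which(mask)) {
    prev <- surv[surv < i]
    nxt <- surv[surv > i]
    if (length(prev) && length(nxt)) {
      out[i] <- (x[max(prev)] + x[min(nxt)]) / 2
    } else if (length(prev)) {
      out[i] <- x[max(prev)]
    } else {
      out[i] <- x[min(nxt)]
    }
  }
  nni_series(out, replaced = mask, times = ppi$peak_times[-1L])
}

#' Construct an NN-interval series
#'
#' @param intervals NN intervals, ms (all > 0).
#' @param replaced Per-interval logical: was this interval imputed?
#' @param times Ending beat time of each interval, seconds.
#' @param start_time Absolute time of the series origin, seconds.
#' @param duration_s Duration of the underlying recording, seconds.
#' @return Object of class `nni_series`.
#' @export
nni_series <- function(intervals, replaced = logical(length(intervals)),
                       times = cumsum(intervals) / 1000, start_time = 0,
                       duration_s = if (length(times)) max(times) else 0) {
  if (any(intervals <= 0)) stop("NN intervals must be strictly positive")
  stopifnot(length(replaced) == length(intervals),
            length(times) == length(intervals))
  structure(
    list(intervals = as.numeric(intervals), replaced = replaced,
         times = as.numeric(times), start_time = start_time,
         duration_s = duration_s),
    class = "nni_series"
  )
}

#' @export
print.nni_series <- function(x, ...) {
  cat(sprintf("<nni_series> %d intervals over %.1f s, mean %.1f ms, %d replaced\n",
              length(x$intervals), x$duration_s, mean(x$intervals),
              sum(x$replaced)))
  invisible(x)
}

#' Full preprocessing pipeline: raw PPG to NN intervals
#'
#' Composition, in order: trim head/tail, band-pass filter, peak detection,
#' single-pass z-score outlier flagging, neighbour-median replacement. Fully
#' deterministic.
#'
#' @param rec A raw `ppg_recording`.
#' @param cfg A [preprocess_config()].
#' @return An `nni_series`; `start_time` is the absolute time of the trimmed
#'   segment's origin and `times` are relative to it.
#' @export
preprocess <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "ppg_recording"), inherits(cfg, "preprocess_config"))
  trimmed <- trim_recording(rec, cfg$trim_head_s, cfg$trim_tail_s)
  filtered <- bandpass(trimmed, cfg$band_low, cfg$band_high)
  ppi <- detect_peaks(filtered)
  ppi <- remove_outlier_ppi(ppi, cfg$z_threshold)
  nni <- replace_removed(ppi)
  nni$start_time <- trimmed$t0
  nni$duration_s <- length(trimmed$samples) / trimmed$fs
  nni
}
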