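#' Canonical order of the 18 time-domain PRV features
#' @export
prv_feature_names <- function() {
  c("mean_nni", "sdnn", "sdsd", "rmssd", "median_nni",
    "nni_50", "pnni_50", "nni_20", "pnni_20", "range_nni",
    "cvsd", "cvnni", "mean_hr", "max_hr", "min_hr", "std_hr",
    "max_nni", "min_nni")
}

#' Compute the 18 time-domain pulse rate variability features
#'
#' Conventions (fixed, matching the common HRV reference libraries):
#' SDs use the sample convention (denominator n-1); `nni_50` / `nni_20` count
#' successive differences strictly greater than 50 / 20 ms in magnitude;
#' `pnni_*` divide those counts by the total number of NN intervals (a
#' proportion in \[0, 1\]); heart-rate statistics are computed on per-beat
#' instantaneous rates `60000 / nn_i`, not on `60000 / mean(nn)`;
#' `median_nni` is the median of the NN intervals themselves; `sdsd` is the
#' sample SD of the successive differences; `cvsd = rmssd / mean_nni` and
#' `cvnni = sdnn / mean_nni`.
#'
#' @param nni An `nni_series` or a bare numeric vector of NN intervals (ms),
#'   at least 3 intervals.
#' @return Named numeric vector of length 18 (see [prv_feature_names()]).
#' @export
compute_features <- function(nni) {
  x <- if (inherits(nni, "nni_series")) nni$intervals else as.numeric(nni)
  if (length(x) < 3L) stop("insufficient data: need at least 3 NN intervals")
  d <- diff(x)
  hr <- 60000 / x
  rmssd <- sqrt(mean(d^2))
  sdnn <- stats::sd(x)
  mean_nni <- mean(x)
  out <- c(
    mean_nni = mean_nni,
    sdnn = sdnn,
    sdsd = stats::sd(d),
    rmssd = rmssd,
    median_nni = stats::median(x),
    nni_50 = sum(abs(d) > 50),
    pnni_50 = sum(abs(d) > 50) / length(x),
    nni_20 = sum(abs(d) > 20),
    pnni_20 = sum(abs(d) > 20) / length(x),
    range_nni = max(x) - min(x),
    cvsd = rmssd / mean_nni,
    cvnni = sdnn / mean_nni,
    mean_hr = mean(hr),
    max_hr = max(hr),
    min_hr = min(hr),
    std_hr = stats::sd(hr),
    max_nni = max(x),
    min_nni = min(x)
  )
  out[prv_feature_names()]
}
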