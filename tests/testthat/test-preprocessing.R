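make_rec <- function(duration_s, fs = 255, value = 0) {
  ppg_recording(rep(value, round(duration_s * fs)), fs = fs)
}

test_that("trimming removes exactly the head and tail", {
  rec <- make_rec(360)
  out <- trim_recording(rec, 30, 30)
  expect_equal(length(out$samples), 76500)  # 300 s at 255 Hz
  expect_equal(out$t0, 30)

  expect_identical(trim_recording(rec, 0, 0)$samples, rec$samples)
  expect_error(trim_recording(make_rec(50), 30, 30), "too short")
})

test_that("band-pass keeps the pulse band and rejects wander and noise", {
  fs <- 255
  t <- (0:(fs * 120 - 1)) / fs
  mid <- seq(fs * 30, fs * 90)  # avoid filtfilt edge transients
  bf <- signal::butter(2, c(0.5, 3.0) / (fs / 2), type = "pass")
  # transfer-function magnitude straight from the designed polynomials
  hmag <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    abs(sum(bf$b * z^(seq_along(bf$b) - 1)) /
          sum(bf$a * z^(seq_along(bf$a) - 1)))
  }

  for (f in c(1.5, 0.1, 10)) {
    rec <- ppg_recording(sin(2 * pi * f * t), fs = fs)
    out_amp <- max(abs(bandpass(rec)$samples[mid]))
    # forward-backward filtering applies |H|^2
    expect_lt(abs(out_amp - hmag(f)^2), 0.05)
    if (f == 1.5) expect_gte(out_amp, 0.95) else expect_lte(out_amp, 0.1)
  }
  expect_error(bandpass(make_rec(10), low = 0.5, high = 200), "fs/2")
})

test_that("peak detection recovers a clean constant-rate train", {
  gt <- generate_nni_series(physio_state("rest", mean_rr = 1000), 60, seed = 1)
  rec <- render_ppg(gt, fs = 255, seed = 1)
  ppi <- detect_peaks(bandpass(rec))
  expect_true(all(ppi$intervals >= 1000 - 2000 / 255))
  expect_true(all(ppi$intervals <= 1000 + 2000 / 255))
  expect_true(all(diff(ppi$peak_times) > 0))
  expect_false(any(ppi$removal_mask))
})

test_that("peak detection enforces the 3 Hz minimum separation and fails on flat input", {
  expect_error(detect_peaks(make_rec(10, value = 1)), "peaks")
  gt <- generate_nni_series(physio_state("exercise_4set", mean_rr = 520), 60,
                            seed = 2)
  rec <- render_ppg(gt, fs = 255, seed = 2)
  ppi <- detect_peaks(bandpass(rec))
  expect_true(all(ppi$intervals >= 1000 / 3))
})

test_that("peak count matches ground truth on a cohort-style recording", {
  st <- default_states()$rest
  gt <- generate_nni_series(st, 360, seed = 8)
  rec <- render_ppg(gt, fs = 255, noise_sd = 0.05, baseline_amp = 0.3,
                    seed = 8, duration_s = 360)
  trimmed <- trim_recording(rec, 30, 30)
  ppi <- detect_peaks(bandpass(trimmed))
  span <- 30 + c(0, length(trimmed$samples) / trimmed$fs)
  n_truth <- sum(gt$pulse_times >= span[1] & gt$pulse_times <= span[2])
  expect_lte(abs(length(ppi$peak_times) - n_truth), 1)
})

test_that("z-score flagging is a single pass with the documented conventions", {
  ppi <- structure(list(peak_times = cumsum(c(0, rep(0.8, 5))),
                        intervals = rep(800, 5),
                        removal_mask = logical(5)),
                   class = "ppi_series")
  expect_false(any(remove_outlier_ppi(ppi)$removal_mask))  # sd = 0 no-op

  x <- c(rep(800, 10), 1600)
  ppi2 <- structure(list(peak_times = cumsum(c(0, x / 1000)),
                         intervals = x, removal_mask = logical(11)),
                    class = "ppi_series")
  out <- remove_outlier_ppi(ppi2, T = 2)
  expect_identical(which(out$removal_mask), 11L)
  expect_identical(out$intervals, x)  # intervals untouched, only mask set
  expect_false(any(remove_outlier_ppi(ppi2, T = 10)$removal_mask))
  expect_error(remove_outlier_ppi(structure(
    list(peak_times = c(0, 0.8, 1.6), intervals = c(800, 800),
         removal_mask = logical(2)), class = "ppi_series")), "3 intervals")
})

test_that("flagged intervals are replaced by nearest-survivor medians", {
  mk <- function(x, mask) structure(
    list(peak_times = cumsum(c(0, x / 1000)), intervals = x,
         removal_mask = mask), class = "ppi_series")

  out <- replace_removed(mk(c(800, 999, 820), c(FALSE, TRUE, FALSE)))
  expect_equal(out$intervals, c(800, 810, 820))
  expect_identical(out$replaced, c(FALSE, TRUE, FALSE))

  out2 <- replace_removed(mk(c(800, 1, 1, 900), c(FALSE, TRUE, TRUE, FALSE)))
  expect_equal(out2$intervals, c(800, 850, 850, 900))

  out3 <- replace_removed(mk(c(5, 700, 710), c(TRUE, FALSE, FALSE)))
  expect_equal(out3$intervals, c(700, 700, 710))

  expect_error(replace_removed(mk(c(1, 2), c(TRUE, TRUE))), "all intervals")
  # length always preserved
  expect_length(out2$intervals, 4)
})

test_that("full pipeline recovers ground truth on a clean recording", {
  st <- default_states()$rest
  gt <- generate_nni_series(st, 360, seed = 3)
  rec <- render_ppg(gt, fs = 255, seed = 3, duration_s = 360)
  nni <- preprocess(rec)

  span_t <- gt$pulse_times[gt$pulse_times >= nni$start_time - 1e-9 &
                             gt$pulse_times <= nni$start_time +
                             nni$duration_s + 1e-9]
  gt_rr <- diff(span_t) * 1000
  expect_lte(abs(length(nni$intervals) - length(gt_rr)), 2)
  n <- min(length(nni$intervals), length(gt_rr))
  err <- abs(nni$intervals[seq_len(n)] - gt_rr[seq_len(n)])
  # boundary beats have truncated pulses, so the first/last interval is
  # excluded from the strict sampling-resolution bound
  interior <- seq(2, n - 1)
  expect_lte(max(err[interior][!nni$replaced[interior]]), 2000 / 255)

  nni2 <- preprocess(rec)
  expect_identical(nni$intervals, nni2$intervals)  # deterministic
  expect_identical(nni$replaced, nni2$replaced)
})

test_that("artifact spikes produce replaced intervals; clean replacement rate stays small", {
  st <- default_states()$rest
  gt <- generate_nni_series(st, 360, seed = 4)
  # spikes mid-diastole (between beats) inside the trimmed span, so each one
  # splits an interval into two strong z-outliers
  spikes <- vapply(c(100, 150, 200), function(at) {
    i <- findInterval(at, gt$pulse_times)
    (gt$pulse_times[i] + gt$pulse_times[i + 1]) / 2
  }, numeric(1))
  rec <- render_ppg(gt, fs = 255, noise_sd = 0.05, seed = 4,
                    artifact_times = spikes, duration_s = 360)
  nni <- preprocess(rec)
  expect_gte(sum(nni$replaced), length(spikes))
  # the flagged intervals cluster at the spike times
  flagged_t <- nni$start_time + nni$times[nni$replaced]
  expect_true(all(vapply(spikes, function(s) any(abs(flagged_t - s) < 2),
                         logical(1))))

  # without artifacts only the jitter tails of the z-rule are replaced
  frac <- vapply(1:20, function(s) {
    g <- generate_nni_series(st, 360, seed = s)
    r <- render_ppg(g, fs = 255, noise_sd = 0.05, seed = s, duration_s = 360)
    nn <- preprocess(r)
    mean(nn$replaced)
  }, numeric(1))
  expect_true(all(frac < 0.10))
})

test_that("preprocess rejects recordings too short for the trim", {
  gt <- generate_nni_series(physio_state("rest", mean_rr = 800), 50, seed = 1)
  rec <- render_ppg(gt, fs = 255, seed = 1)
  expect_error(preprocess(rec), "too short")
})
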