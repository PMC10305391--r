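test_that("noise-free generation reproduces the requested beat spacing", {
  st <- physio_state("rest", mean_rr = 850)
  gt <- generate_nni_series(st, 60, seed = 1)
  expect_true(all(abs(gt$rr_intervals - 850) < 1e-9))
  expect_true(length(gt$pulse_times) %in% 70:72)  # 60000/850 ~ 70.6 beats

  st2 <- physio_state("exercise_4set", mean_rr = 500)
  gt2 <- generate_nni_series(st2, 120, seed = 1)
  expect_equal(mean(60000 / gt2$rr_intervals), 120)
})

test_that("generation rejects invalid durations and degenerate parameters", {
  st <- physio_state("rest", mean_rr = 850)
  expect_error(generate_nni_series(st, 0), "positive")
  expect_error(generate_nni_series(st, -5), "positive")
  bad <- physio_state("rest", mean_rr = 400, rr_jitter_sd = 400)
  expect_error(generate_nni_series(bad, 300, seed = 2), "non-positive")
})

test_that("sample SDNN matches the sinusoid-plus-noise closed form", {
  # Var(rr) = jitter^2 + sum(amp^2)/2 for sinusoidal modulators with
  # incommensurate frequencies; rest state: sqrt(900 + 800 + 312.5) ~ 44.9 ms
  st <- default_states()$rest
  expected_sd <- sqrt(st$rr_jitter_sd^2 +
                        (st$resp_mod_amp^2 + st$lf_mod_amp^2) / 2)
  expect_gt(expected_sd, 35)
  expect_lt(expected_sd, 65)
  hits <- vapply(1:200, function(s) {
    sdnn <- sd(generate_nni_series(st, 300, seed = s)$rr_intervals)
    sdnn >= 35 && sdnn <= 65
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("rendered waveform peaks sit at the beat times", {
  st <- physio_state("rest", mean_rr = 1000)
  gt <- generate_nni_series(st, 30, seed = 1)
  rec <- render_ppg(gt, fs = 255, seed = 1, duration_s = 30.5)
  x <- rec$samples
  i <- 2:(length(x) - 1)
  peaks <- i[x[i] > x[i - 1] & x[i] >= x[i + 1] & x[i] > 0.5]
  peak_t <- (peaks - 1) / 255
  interior <- gt$pulse_times[-1]  # the t = 0 beat peaks on the first sample
  expect_equal(length(peak_t), length(interior))
  expect_true(all(abs(peak_t - interior) <= 1 / 255 + 1e-12))
  # noiseless constant-rate train is periodic with the beat period
  expect_true(all(abs(diff(peak_t) - 1.0) <= 2 / 255 + 1e-12))
})

test_that("rendering is deterministic in the seed and sensitive to it", {
  gt <- generate_nni_series(default_states()$rest, 40, seed = 5)
  a <- render_ppg(gt, noise_sd = 0.05, artifact_rate = 2, seed = 9)
  b <- render_ppg(gt, noise_sd = 0.05, artifact_rate = 2, seed = 9)
  expect_identical(a$samples, b$samples)
  c <- render_ppg(gt, noise_sd = 0.05, artifact_rate = 2, seed = 10)
  expect_false(identical(a$samples, c$samples))
  expect_error(render_ppg(gt, fs = 4), "fs")
})

test_that("cohort has n_subjects x n_states recordings and is reproducible", {
  cfg <- synth_config(n_subjects = 2, duration_s = 120, seed = 11)
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 2 * 3)
  cohort2 <- generate_cohort(cfg)
  expect_identical(cohort[[1]]$recording$samples,
                   cohort2[[1]]$recording$samples)
  expect_identical(cohort[[6]]$truth$rr_intervals,
                   cohort2[[6]]$truth$rr_intervals)
  cfg2 <- synth_config(n_subjects = 2, duration_s = 120, seed = 12)
  cohort3 <- generate_cohort(cfg2)
  expect_false(identical(cohort[[1]]$recording$samples,
                         cohort3[[1]]$recording$samples))

  one <- generate_cohort(synth_config(states = default_states()["rest"],
                                      n_subjects = 1, duration_s = 120,
                                      seed = 1))
  expect_length(one, 1)
  expect_true(abs(length(one[[1]]$recording$samples) - 120 * 255) <= 1)
})

test_that("default study cohort is 17 subjects x 3 states = 51 recordings", {
  cfg <- synth_config(seed = 1)
  expect_equal(cfg$n_subjects * length(cfg$states), 51)
})

test_that("every cohort recording stays in the 60-180 bpm band", {
  cohort <- generate_cohort(synth_config(n_subjects = 4, duration_s = 120,
                                         seed = 21))
  bpm <- vapply(cohort, function(el) 60000 / mean(el$truth$rr_intervals),
                numeric(1))
  expect_true(all(bpm >= 60 & bpm <= 180))
})

test_that("config validation enforces the study design constraints", {
  expect_error(synth_config(duration_s = 100), "120")
  expect_error(synth_config(fs = 4), "fs")
  sts <- default_states()
  sts$exercise_2set <- physio_state("exercise_2set", mean_rr = 900)
  expect_error(synth_config(states = sts), "exercise")
  expect_error(physio_state("rest", mean_rr = 2000), "330")
  expect_error(physio_state("rest", mean_rr = 800, rr_jitter_sd = -1), ">= 0")
})
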