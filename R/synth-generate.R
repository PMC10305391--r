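#' Generate a ground-truth NN-interval series for one recording
#'
#' Beat times are laid down sequentially; each interval is the state's mean RR
#' plus sinusoidal respiratory and low-frequency modulation evaluated at the
#' current beat time, plus Gaussian jitter:
#' \deqn{rr_i = \bar{rr} + a_r \sin(2\pi f_r t_i + \phi_r) +
#'       a_l \sin(2\pi f_l t_i + \phi_l) + \epsilon_i,\quad
#'       \epsilon_i \sim N(0, \sigma^2).}
#' Modulation phases are drawn uniformly per recording so sliding windows are
#' not phase-locked to the modulators.
#'
#' @param state A [physio_state()].
#' @param duration_s Positive recording duration in seconds.
#' @param seed Integer seed; the output is a pure function of
#'   `(state, duration_s, seed)`.
#' @return An object of class `ground_truth` with fields `pulse_times`
#'   (seconds, first beat at t = 0), `rr_intervals` (ms, successive
#'   differences of the pulse times), and `state`.
#' @export
generate_nni_series <- function(state, duration_s, seed = 1L) {
  stopifnot(inherits(state, "physio_state"))
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0) {
    stop("`duration_s` must be a positive number")
  }
  withr::with_seed(as.integer(seed), {
    phase_r <- stats::runif(1, 0, 2 * pi)
    phase_l <- stats::runif(1, 0, 2 * pi)
    # upper bound on beat count, +8 margin for jitter
    n_max <- ceiling(duration_s * 1000 / max(state$mean_rr - 6 * state$rr_jitter_sd -
                                               state$resp_mod_amp - state$lf_mod_amp, 200)) + 8L
    eps <- stats::rnorm(n_max, 0, state$rr_jitter_sd)
    times <- numeric(n_max + 1L)
    rr <- numeric(n_max)
    t <- 0
    i <- 0L
    while (t <= duration_s && i < n_max) {
      i <- i + 1L
      r <- state$mean_rr +
        state$resp_mod_amp * sin(2 * pi * state$resp_mod_freq * t + phase_r) +
        state$lf_mod_amp * sin(2 * pi * state$lf_mod_freq * t + phase_l) +
        eps[i]
      if (r <= 0) {
        stop("state parameters yielded a non-positive RR interval")
      }
      rr[i] <- r
      t <- t + r / 1000
      times[i + 1L] <- t
    }
    keep <- which(times[seq_len(i + 1L)] <= duration_s)
    pulse_times <- times[keep]
    structure(
      list(pulse_times = pulse_times,
           rr_intervals = diff(pulse_times) * 1000,
           state = state),
      class = "ground_truth"
    )
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s: %d beats over %.1f s, mean RR %.1f ms\n",
              x$state$name, length(x$pulse_times),
              max(x$pulse_times), mean(x$rr_intervals)))
  invisible(x)
}

# Unit-height pulse template (seconds): asymmetric systolic peak plus a
# smaller dicrotic bump 250 ms later, mimicking a finger-PPG beat morphology.
# Only the peak *time* matters downstream, so the exact shape is free; the
# bump delay keeps the (filter-smeared) bump inside the detector's fs/3
# refractory distance so it is never mistaken for a beat.
ppg_pulse_template <- function(t) {
  exp(-t^2 / (2 * 0.06^2)) + 0.3 * exp(-(t - 0.25)^2 / (2 * 0.08^2))
}

#' Render a PPG waveform from ground-truth beat times
#'
#' Sums a fixed pulse template at each beat time, adds sinusoidal baseline
#' wander and white noise, and optionally injects transient amplitude-spike
#' artifacts at Poisson-distributed times (or at caller-supplied times, which
#' is useful for controlled artifact bookkeeping). Local maxima of the
#' noise-free, wander-free rendering coincide with the beat times to within
#' one sample period.
#'
#' @param truth A `ground_truth` object.
#' @param fs Sampling rate, Hz (>= 6).
#' @param noise_sd Additive Gaussian noise SD (a.u.; pulse height is 1).
#' @param baseline_amp,baseline_freq Baseline-wander sinusoid (a.u., Hz).
#' @param artifact_rate Spike artifacts per minute (Poisson); ignored when
#'   `artifact_times` is given.
#' @param seed Integer seed (noise, artifact times).
#' @param artifact_times Optional numeric vector of artifact centres (s).
#' @param duration_s Length of the rendered time grid, s; defaults to the
#'   last beat time.
#' @return A `ppg_recording`: `samples`, `fs`, `subject_id`, `state`, `t0`,
#'   plus the realised `artifact_times`.
#' @export
render_ppg <- function(truth, fs = 255, noise_sd = 0, baseline_amp = 0,
                       baseline_freq = 0.1, artifact_rate = 0, seed = 1L,
                       artifact_times = NULL, duration_s = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (fs < 6) stop("`fs` must be >= 6 Hz to resolve the pulse band")
  duration <- if (is.null(duration_s)) max(truth$pulse_times) else duration_s
  n <- floor(duration * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  withr::with_seed(as.integer(seed), {
    x <- numeric(n)
    half_w <- 0.7  # template support, s
    for (p in truth$pulse_times) {
      i0 <- max(1L, floor((p - half_w) * fs) + 1L)
      i1 <- min(n, ceiling((p + half_w) * fs) + 1L)
      idx <- i0:i1
      x[idx] <- x[idx] + ppg_pulse_template(t[idx] - p)
    }
    if (is.null(artifact_times)) {
      n_art <- stats::rpois(1, artifact_rate * duration / 60)
      artifact_times <- sort(stats::runif(n_art, 0, duration))
    }
    for (a in artifact_times) {
      i0 <- max(1L, floor((a - 0.1) * fs) + 1L)
      i1 <- min(n, ceiling((a + 0.1) * fs) + 1L)
      idx <- i0:i1
      x[idx] <- x[idx] + 4 * exp(-(t[idx] - a)^2 / (2 * 0.02^2))
    }
    if (baseline_amp > 0) {
      x <- x + baseline_amp * sin(2 * pi * baseline_freq * t)
    }
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    ppg_recording(x, fs = fs, subject_id = NA_character_,
                  state = truth$state$name, t0 = 0,
                  artifact_times = artifact_times)
  })
}

#' Generate a full synthetic cohort
#'
#' Produces `n_subjects` x `length(states)` recordings. Each subject gets a
#' seeded perturbation of every state's parameters (mean RR shifted by
#' N(0, 40 ms) and clamped to the 60-180 bpm band; variability amplitudes
#' scaled by U(0.85, 1.15)), emulating between-subject physiology. The whole
#' cohort is reproducible from `config$seed`.
#'
#' @param config A [synth_config()].
#' @return List of length `n_subjects * length(states)`; each element has
#'   `recording` (a `ppg_recording`) and `truth` (a `ground_truth`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  recs <- vector("list", config$n_subjects * length(config$states))
  withr::with_seed(config$seed, {
    rec_seeds <- sample.int(.Machine$integer.max, 2L * length(recs))
    shift <- stats::rnorm(config$n_subjects * length(config$states), 0, 40)
    scale <- stats::runif(config$n_subjects * length(config$states), 0.85, 1.15)
  })
  i <- 0L
  for (k in seq_len(config$n_subjects)) {
    for (st in config$states) {
      i <- i + 1L
      mean_rr <- min(max(st$mean_rr + shift[i], 360), 990)
      subj_state <- physio_state(
        st$name, mean_rr = mean_rr,
        rr_jitter_sd = st$rr_jitter_sd * scale[i],
        resp_mod_amp = st$resp_mod_amp * scale[i],
        resp_mod_freq = st$resp_mod_freq,
        lf_mod_amp = st$lf_mod_amp * scale[i],
        lf_mod_freq = st$lf_mod_freq)
      truth <- generate_nni_series(subj_state, config$duration_s,
                                   seed = rec_seeds[2L * i - 1L])
      rec <- render_ppg(truth, fs = config$fs, noise_sd = config$noise_sd,
                        baseline_amp = config$baseline_amp,
                        baseline_freq = config$baseline_freq,
                        artifact_rate = config$artifact_rate,
                        seed = rec_seeds[2L * i],
                        duration_s = config$duration_s)
      rec$subject_id <- sprintf("subject%02d", k)
      recs[[i]] <- list(recording = rec, truth = truth)
    }
  }
  recs
}
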