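#' Physiological state parameters for the beat-interval model
#'
#' A state bundles the parameters of the RR-interval model used by
#' [generate_nni_series()]: a mean interbeat interval, sinusoidal respiratory
#' (~0.25 Hz) and low-frequency (~0.1 Hz) modulation amplitudes, and the
#' standard deviation of beat-to-beat Gaussian jitter. Exercise recovery is
#' characterised by a shorter mean interval (higher heart rate) and reduced
#' variability, which is what drives the stress index up after exertion.
#'
#' @param name State label, one of `"rest"`, `"exercise_2set"`,
#'   `"exercise_4set"`.
#' @param mean_rr Mean RR interval in ms; must lie in \[330, 1500\]
#'   (60-180 bpm).
#' @param rr_jitter_sd SD of beat-to-beat Gaussian jitter, ms.
#' @param resp_mod_amp,resp_mod_freq Amplitude (ms) and frequency (Hz) of the
#'   respiratory sinus modulation.
#' @param lf_mod_amp,lf_mod_freq Amplitude (ms) and frequency (Hz) of the
#'   low-frequency (baroreflex-band) modulation.
#' @return An object of class `physio_state`.
#' @seealso [default_states()] for the three study states.
#' @export
physio_state <- function(name, mean_rr, rr_jitter_sd = 0,
                         resp_mod_amp = 0, resp_mod_freq = 0.25,
                         lf_mod_amp = 0, lf_mod_freq = 0.1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(mean_rr) || length(mean_rr) != 1L ||
      mean_rr < 330 || mean_rr > 1500) {
    stop("`mean_rr` must be a single value in [330, 1500] ms (60-180 bpm)")
  }
  amps <- c(rr_jitter_sd, resp_mod_amp, lf_mod_amp)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    stop("jitter and modulation amplitudes must be finite and >= 0")
  }
  structure(
    list(name = name, mean_rr = mean_rr, rr_jitter_sd = rr_jitter_sd,
         resp_mod_amp = resp_mod_amp, resp_mod_freq = resp_mod_freq,
         lf_mod_amp = lf_mod_amp, lf_mod_freq = lf_mod_freq),
    class = "physio_state"
  )
}

#' @export
print.physio_state <- function(x, ...) {
  cat(sprintf(
    "<physio_state> %s: mean RR %.0f ms (%.1f bpm), jitter SD %.0f ms, resp %.0f ms @ %.2f Hz, LF %.0f ms @ %.2f Hz\n",
    x$name, x$mean_rr, 60000 / x$mean_rr, x$rr_jitter_sd,
    x$resp_mod_amp, x$resp_mod_freq, x$lf_mod_amp, x$lf_mod_freq))
  invisible(x)
}

#' Default rest and post-exercise state parameters
#'
#' Mean RR shortens and variability shrinks from rest through two to four sets
#' of push-ups: 850 / 650 / 520 ms. The 520 ms extreme keeps every subject's
#' instantaneous heart rate under the 180 bpm physiological ceiling while
#' allowing maxima in the high 150s, matching the intensity of short intense
#' exercise. Variability (jitter + both modulators) shrinks monotonically with
#' intensity, so exercise states produce narrower, taller interval histograms
#' and hence higher stress indices.
#'
#' @return Named list of three `physio_state` objects.
#' @export
default_states <- function() {
  list(
    rest = physio_state("rest", mean_rr = 850, rr_jitter_sd = 30,
                        resp_mod_amp = 40, resp_mod_freq = 0.25,
                        lf_mod_amp = 25, lf_mod_freq = 0.10),
    exercise_2set = physio_state("exercise_2set", mean_rr = 650,
                                 rr_jitter_sd = 14, resp_mod_amp = 18,
                                 resp_mod_freq = 0.30, lf_mod_amp = 11,
                                 lf_mod_freq = 0.10),
    exercise_4set = physio_state("exercise_4set", mean_rr = 520,
                                 rr_jitter_sd = 7, resp_mod_amp = 9,
                                 resp_mod_freq = 0.33, lf_mod_amp = 5,
                                 lf_mod_freq = 0.10)
  )
}

total_modulation <- function(state) {
  state$rr_jitter_sd + state$resp_mod_amp + state$lf_mod_amp
}

#' Synthetic cohort configuration
#'
#' @param states List of `physio_state` objects; defaults to
#'   [default_states()]. If a `"rest"` state is present, every exercise state
#'   must have a shorter mean RR and less total modulation than rest.
#' @param n_subjects Number of subjects (default 17).
#' @param duration_s Recording length in seconds (default 360, i.e. 6 min);
#'   must be >= 120 so a recording survives the 30 s + 30 s trim and still
#'   holds at least one 60 s label window.
#' @param fs Sampling rate in Hz (default 255); must be >= 6 (twice the 3 Hz
#'   upper band edge of the preprocessing filter).
#' @param noise_sd Additive white-noise SD, in units of the unit-height pulse.
#' @param baseline_amp,baseline_freq Baseline-wander sinusoid amplitude (a.u.)
#'   and frequency (Hz); the default 0.1 Hz sits below the filter passband.
#' @param artifact_rate Transient amplitude-spike artifacts, events per minute.
#' @param seed Integer master seed; the whole cohort is a pure function of the
#'   configuration.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(states = default_states(), n_subjects = 17,
                         duration_s = 360, fs = 255, noise_sd = 0.05,
                         baseline_amp = 0.3, baseline_freq = 0.1,
                         artifact_rate = 0.5, seed = 1L) {
  stopifnot(length(states) >= 1L,
            all(vapply(states, inherits, logical(1), "physio_state")))
  if (duration_s < 120) {
    stop("`duration_s` must be >= 120 s (trim + one 60 s label window)")
  }
  if (fs < 6) stop("`fs` must be >= 6 Hz (twice the 3 Hz band edge)")
  stopifnot(n_subjects >= 1, noise_sd >= 0, baseline_amp >= 0,
            artifact_rate >= 0)
  names(states) <- vapply(states, `[[`, character(1), "name")
  if ("rest" %in% names(states)) {
    rest <- states[["rest"]]
    for (st in states) {
      if (st$name == "rest") next
      if (st$mean_rr >= rest$mean_rr ||
          total_modulation(st) >= total_modulation(rest)) {
        stop("exercise states must have smaller mean RR and smaller total ",
             "modulation than rest")
      }
    }
  }
  structure(
    list(states = states, n_subjects = n_subjects, duration_s = duration_s,
         fs = fs, noise_sd = noise_sd, baseline_amp = baseline_amp,
         baseline_freq = baseline_freq, artifact_rate = artifact_rate,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}
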