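#' Write / read a PPG recording as two-column CSV
#'
#' Columns `t_s` (sample times, seconds) and `amplitude` (a.u.); the sampling
#' rate travels in a sidecar manifest or is recovered from the time column.
#'
#' @param rec A `ppg_recording`.
#' @param path Output CSV path.
#' @export
write_ppg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "ppg_recording"))
  t_s <- rec$t0 + (seq_along(rec$samples) - 1L) / rec$fs
  utils::write.csv(data.frame(t_s = t_s, amplitude = rec$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ppg_csv
#' @param fs Sampling rate; if `NULL`, inferred from the median time step.
#' @param subject_id,state Labels attached to the recording.
#' @export
read_ppg_csv <- function(path, fs = NULL, subject_id = NA_character_,
                         state = NA_character_) {
  df <- utils::read.csv(path)
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$t_s))
  ppg_recording(df$amplitude, fs = fs, subject_id = subject_id,
                state = state, t0 = df$t_s[1])
}

#' Write / read an NN-interval series as CSV
#'
#' Columns `nn_ms` and `replaced`; a bare single-column `nn_ms` file is also
#' accepted on read.
#'
#' @param nni An `nni_series`.
#' @param path CSV path.
#' @export
write_nni_csv <- function(nni, path) {
  stopifnot(inherits(nni, "nni_series"))
  utils::write.csv(data.frame(nn_ms = nni$intervals,
                              replaced = nni$replaced),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nni_csv
#' @export
read_nni_csv <- function(path) {
  df <- utils::read.csv(path)
  replaced <- if ("replaced" %in% names(df)) as.logical(df$replaced) else
    logical(nrow(df))
  nni_series(df$nn_ms, replaced = replaced)
}
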