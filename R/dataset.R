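#' Slide feature/label windows over an NN-interval series
#'
#' Window starts run from 0 in steps of `stride` up to
#' `duration - label_len`, so the sample count per recording does not depend
#' on the feature window length `L`: every length's dataset shares identical
#' labels and only the features change. An interval belongs to a window when
#' its *ending* beat time falls inside it. Features are computed from
#' \[t, t + L) and the label is the square root of the Baevsky SI over
#' \[t, t + `label_len`). Windows with fewer than 3 feature intervals or a
#' degenerate label segment (zero interval range) are dropped; the dropped
#' count is kept in the `n_dropped` attribute.
#'
#' @param nni An `nni_series` (with `times` and `duration_s` set).
#' @param L Feature window length, s; must be <= `label_len`.
#' @param stride Window stride, s (default 1).
#' @param label_len Label window length, s (default 60).
#' @param recording_id Label stored in the output rows.
#' @return Data frame: `recording_id`, `t_start`, `window_len`, the 18
#'   feature columns, and `label`.
#' @export
slide_windows <- function(nni, L, stride = 1, label_len = 60,
                          recording_id = "rec") {
  stopifnot(inherits(nni, "nni_series"))
  if (L > label_len) stop("invalid argument: L must be <= label_len")
  if (L <= 0 || stride <= 0) stop("invalid argument: L and stride must be > 0")
  if (nni$duration_s < label_len) {
    stop("recording shorter than the label window")
  }
  starts <- seq(0, nni$duration_s - label_len, by = stride)
  times <- nni$times
  eps <- 1e-9
  rows <- vector("list", length(starts))
  n_dropped <- 0L
  for (j in seq_along(starts)) {
    t <- starts[j]
    f_lo <- findInterval(t - eps, times) + 1L
    f_hi <- findInterval(t + L - eps, times)
    l_hi <- findInterval(t + label_len - eps, times)
    if (f_hi - f_lo + 1L < 3L || l_hi - f_lo + 1L < 2L) {
      n_dropped <- n_dropped + 1L
      next
    }
    lab_x <- nni$intervals[f_lo:l_hi]
    if (max(lab_x) == min(lab_x)) {  # degenerate SI segment
      n_dropped <- n_dropped + 1L
      next
    }
    feats <- compute_features(nni$intervals[f_lo:f_hi])
    lab <- compute_si(lab_x)$sqrt_si
    rows[[j]] <- c(t_start = t, feats, label = lab)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  mat <- do.call(rbind, rows)
  out <- data.frame(recording_id = recording_id,
                    t_start = mat[, "t_start"],
                    window_len = L,
                    mat[, c(prv_feature_names(), "label"), drop = FALSE],
                    row.names = NULL)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Agreement between short-window and full-length reference features
#'
#' For each feature, pairs every window sample with the value computed from
#' its source recording's full-length (5 min) NN series and scores the
#' agreement as a coefficient of determination with the reference as target:
#' \deqn{R^2_f = 1 - \sum_i (ref_i - short_i)^2 / \sum_i (ref_i -
#' \overline{ref})^2.}
#' Values can be negative when the short-window feature disagrees with the
#' reference more than a constant predictor would. A feature whose reference
#' values have zero variance gets `NA` (undefined).
#'
#' @param samples Data frame from [slide_windows()] (possibly several
#'   recordings row-bound), containing `recording_id` and feature columns.
#' @param references Matrix or data frame of full-length feature vectors, one
#'   row per recording, rownames = recording ids.
#' @param features Feature columns to score (default all 18).
#' @param threshold Selection threshold carried in the report (default 0.6).
#' @return Object of class `feature_selection_report`: data frame
#'   `feature`/`r2`, plus `threshold` and `selected` (names with
#'   `r2 >= threshold`, order-stable).
#' @export
feature_reference_r2 <- function(samples, references,
                                 features = prv_feature_names(),
                                 threshold = 0.6) {
  references <- as.matrix(references)
  if (!all(unique(samples$recording_id) %in% rownames(references))) {
    stop("every sampled recording needs a reference feature vector")
  }
  idx <- match(samples$recording_id, rownames(references))
  r2 <- vapply(features, function(f) {
    ref <- references[idx, f]
    sst <- sum((ref - mean(ref))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((ref - samples[[f]])^2) / sst
  }, numeric(1))
  report <- list(scores = data.frame(feature = features, r2 = unname(r2)),
                 threshold = threshold,
                 selected = features[!is.na(r2) & r2 >= threshold])
  class(report) <- "feature_selection_report"
  report
}

#' @export
print.feature_selection_report <- function(x, ...) {
  cat(sprintf("<feature_selection_report> %d/%d features with R2 >= %.2f: %s\n",
              length(x$selected), nrow(x$scores), x$threshold,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Select features whose agreement score clears the threshold
#'
#' @param report A `feature_selection_report`, or a named numeric vector of
#'   per-feature agreement scores.
#' @param threshold Minimum R2 (default 0.6).
#' @return Character vector of selected feature names, in the report's
#'   (stable) order.
#' @export
select_features <- function(report, threshold = 0.6) {
  if (inherits(report, "feature_selection_report")) {
    r2 <- stats::setNames(report$scores$r2, report$scores$feature)
  } else {
    r2 <- report
  }
  sel <- names(r2)[!is.na(r2) & r2 >= threshold]
  if (length(sel) == 0L) stop("empty selection: no feature reached R2 >= ",
                              threshold)
  sel
}

#' Scale feature rows to unit L2 norm
#'
#' Per-sample normalisation (the "normalizer" scaling): each row of the
#' feature matrix is divided by its Euclidean norm, so rows lie on the unit
#' sphere. Idempotent. `method = "zscore"` standardises columns instead
#' (mean 0, SD 1), for sensitivity analysis.
#'
#' @param x Numeric matrix, samples in rows.
#' @param method `"l2"` (default) or `"zscore"`.
#' @return The scaled matrix.
#' @export
scale_features <- function(x, method = c("l2", "zscore")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (method == "l2") {
    nrm <- sqrt(rowSums(x^2))
    if (any(nrm == 0)) stop("invalid input: zero feature row cannot be scaled")
    x / nrm
  } else {
    scale(x)[, , drop = FALSE]
  }
}

#' Build the windowed regression dataset for one feature window length
#'
#' Slides windows over every recording, scores short-vs-reference feature
#' agreement, keeps features with R2 >= `threshold`, and row-normalises the
#' selected feature matrix. Selection runs on the full pooled sample set
#' before any CV split (mirroring the study workflow); the optimistic bias
#' this introduces is deliberate and documented.
#'
#' @param nni_list Named list of `nni_series` (names = recording ids).
#' @param L Feature window length, s.
#' @param stride,label_len See [slide_windows()].
#' @param threshold Feature-selection threshold (default 0.6).
#' @param scaling Passed to [scale_features()].
#' @return Object of class `window_dataset`: `samples` (data frame),
#'   `selection` (report), `selected_features`, `x` (scaled matrix),
#'   `y` (labels), `groups` (recording ids), `window_len`, `n_dropped`.
#' @export
build_dataset <- function(nni_list, L, stride = 1, label_len = 60,
                          threshold = 0.6, scaling = "l2") {
  stopifnot(length(nni_list) >= 1L, !is.null(names(nni_list)))
  refs <- t(vapply(nni_list, compute_features,
                   numeric(length(prv_feature_names()))))
  parts <- lapply(names(nni_list), function(id) {
    slide_windows(nni_list[[id]], L = L, stride = stride,
                  label_len = label_len, recording_id = id)
  })
  n_dropped <- sum(vapply(parts, function(p) attr(p, "n_dropped"), integer(1)))
  samples <- do.call(rbind, parts)
  report <- feature_reference_r2(samples, refs, threshold = threshold)
  selected <- select_features(report, threshold)
  x <- scale_features(as.matrix(samples[, selected, drop = FALSE]),
                      method = scaling)
  structure(
    list(samples = samples, selection = report, selected_features = selected,
         x = x, y = samples$label, groups = samples$recording_id,
         window_len = L, n_dropped = n_dropped),
    class = "window_dataset"
  )
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf("<window_dataset> L = %g s: %d samples, %d selected features (%s), %d windows dropped\n",
              x$window_len, nrow(x$samples), length(x$selected_features),
              paste(x$selected_features, collapse = ", "), x$n_dropped))
  invisible(x)
}
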