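#' Published short-vs-5-min feature agreement scores
#'
#' The original study's reported R2 agreement between each candidate PRV
#' feature computed on short windows (5-60 s) and the same feature on the
#' full 5-min recording, for the nine features it tabulates. These printed
#' values are inputs to the feature-selection rule (R2 >= 0.6) and let the
#' rule be checked against the reported selected-feature counts.
#'
#' @return Numeric matrix, rows = window lengths (`"5s"`..`"60s"`), columns =
#'   the nine tabulated features.
#' @export
published_feature_agreement <- function() {
  path <- system.file("extdata", "study_feature_agreement_r2.csv",
                      package = "prvstress", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- paste0(df$window_len_s, "s")
  m
}

#' Published model-by-window-length prediction scores
#'
#' The original study's reported mean 10-fold CV R2 of the four regressors at
#' each feature window length, on its (non-shareable) human cohort. Used as
#' input to the per-length summarisation rule.
#'
#' @return Numeric matrix, rows = models, columns = window lengths.
#' @export
published_model_scores <- function() {
  path <- system.file("extdata", "study_model_r2_grid.csv",
                      package = "prvstress", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$model
  m
}
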