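#' Specify one of the four regressors
#'
#' The grid uses four model families: extremely randomised trees
#' (`"extra_trees"`; ranger with random split points and no resampling),
#' gradient-boosted trees (`"gradient_boosting"`; xgboost with the classic
#' boosting defaults: 100 rounds, learning rate 0.1, depth 3), k-nearest
#' neighbours (`"knn"`; k = 5) and ordinary least squares (`"linear"`).
#' Hyperparameters may be overridden via `hyperparameters`; everything used
#' ends up in the fitted object so runs are fully reproducible.
#'
#' @param name One of `"extra_trees"`, `"gradient_boosting"`, `"knn"`,
#'   `"linear"`.
#' @param hyperparameters Named list of overrides.
#' @param seed Integer seed for the model's internal randomness.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(name = c("extra_trees", "gradient_boosting", "knn",
                                "linear"),
                       hyperparameters = list(), seed = 1L) {
  name <- match.arg(name)
  defaults <- switch(name,
    extra_trees = list(num.trees = 100, num.random.splits = 1,
                       min.node.size = 5),
    gradient_boosting = list(nrounds = 100, eta = 0.1, max_depth = 3),
    knn = list(k = 5),
    linear = list())
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(name = name, hyperparameters = hp, seed = as.integer(seed)),
            class = "model_spec")
}

#' All four default model specifications
#' @param seed Seed shared by the stochastic models.
#' @return Named list of `model_spec` objects.
#' @export
default_models <- function(seed = 1L) {
  nm <- c("extra_trees", "gradient_boosting", "knn", "linear")
  stats::setNames(lapply(nm, model_spec, seed = seed), nm)
}

fit_regressor <- function(spec, x, y) {
  hp <- spec$hyperparameters
  fit <- switch(spec$name,
    extra_trees = ranger::ranger(
      x = as.data.frame(x), y = y,
      num.trees = hp$num.trees, mtry = ncol(x),
      splitrule = "extratrees", num.random.splits = hp$num.random.splits,
      replace = FALSE, sample.fraction = 1,
      min.node.size = hp$min.node.size,
      seed = spec$seed, num.threads = 1),
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eta = hp$eta,
                    max_depth = hp$max_depth, subsample = 1,
                    colsample_bytree = 1, nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
      nrounds = hp$nrounds, verbose = 0),
    knn = caret::knnreg(as.data.frame(x), y, k = hp$k),
    linear = stats::lm(label ~ ., data = cbind(as.data.frame(x), label = y)))
  structure(list(spec = spec, fit = fit), class = "prv_regressor")
}

predict_regressor <- function(model, x) {
  x <- as.data.frame(x)
  switch(model$spec$name,
    extra_trees = stats::predict(model$fit, data = x,
                                 num.threads = 1)$predictions,
    gradient_boosting = stats::predict(model$fit,
                                       xgboost::xgb.DMatrix(as.matrix(x))),
    knn = stats::predict(model$fit, x),
    linear = unname(stats::predict(model$fit, newdata = x)))
}

#' Coefficient of determination
#'
#' `1 - sum((actual - predicted)^2) / sum((actual - mean(actual))^2)`, with
#' the mean of `actual` as the baseline; can be negative.
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @return A single number.
#' @export
r2_score <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  1 - sum((actual - predicted)^2) / sum((actual - mean(actual))^2)
}

#' k-fold cross-validated evaluation of one model on one dataset
#'
#' Samples (default) or whole recordings (`group_by = "recording"`) are
#' shuffled into `k` folds under `seed`; each fold is scored as the R2 of its
#' out-of-fold predictions against the held-out labels (held-out mean as
#' baseline). Sample-level folds reproduce the study protocol but are
#' optimistic, because 1-s-stride windows overlap heavily and near-duplicate
#' windows land in both train and test; grouped folds quantify that optimism.
#'
#' @param dataset A `window_dataset`.
#' @param model A `model_spec`.
#' @param k Number of folds (default 10); needs `k` <= number of samples
#'   (or of recordings, when grouped).
#' @param seed Integer seed for fold assignment.
#' @param group_by `"none"` (sample-level folds) or `"recording"`.
#' @return List: `mean_r2`, `fold_scores` (length `k`), `oof` (data frame
#'   `actual` / `predicted` / `fold`, one row per sample), `model`, `k`.
#' @export
cross_validate <- function(dataset, model, k = 10, seed = 1L,
                           group_by = c("none", "recording")) {
  stopifnot(inherits(dataset, "window_dataset"), inherits(model, "model_spec"))
  group_by <- match.arg(group_by)
  n <- length(dataset$y)
  if (group_by == "none") {
    if (n < k) stop("invalid input: fewer samples than folds")
    fold <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  } else {
    recs <- unique(dataset$groups)
    if (length(recs) < k) stop("invalid input: fewer recordings than folds")
    rec_fold <- withr::with_seed(seed,
                                 sample(rep_len(seq_len(k), length(recs))))
    fold <- rec_fold[match(dataset$groups, recs)]
  }
  pred <- numeric(n)
  scores <- numeric(k)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- fit_regressor(model, dataset$x[!test, , drop = FALSE],
                         dataset$y[!test])
    pred[test] <- predict_regressor(fit, dataset$x[test, , drop = FALSE])
    scores[f] <- r2_score(dataset$y[test], pred[test])
  }
  list(mean_r2 = mean(scores), fold_scores = scores,
       oof = data.frame(actual = dataset$y, predicted = pred, fold = fold),
       model = model$name, k = k)
}

#' Out-of-fold predicted-vs-actual pairs for scatter plots
#'
#' @param cv Result of [cross_validate()].
#' @return Data frame with one `predicted` / `actual` pair per sample.
#' @export
scatter_export <- function(cv) {
  data.frame(predicted = cv$oof$predicted, actual = cv$oof$actual)
}

#' Run the full model x window-length evaluation grid
#'
#' For each feature window length, builds the windowed dataset (shared
#' labels, per-length feature selection and scaling) and evaluates all four
#' regressors with k-fold CV, producing the model x length grid of mean CV
#' R2 scores plus the per-length average row.
#'
#' @param nni_list Named list of preprocessed `nni_series`.
#' @param lengths Feature window lengths in seconds
#'   (default `c(5, 10, 20, 30, 40, 50, 60)`).
#' @param models Named list of `model_spec`s (default [default_models()]).
#' @param k Folds (default 10).
#' @param seed Seed for fold assignment and stochastic models.
#' @param group_by Passed to [cross_validate()].
#' @param stride,label_len,threshold,scaling Passed to [build_dataset()].
#' @param keep_oof Keep per-cell out-of-fold predictions (default TRUE).
#' @return Object of class `experiment_result`: `grid` (models x lengths
#'   matrix of mean CV R2), `mean_row`, `fold_scores`, `n_samples`,
#'   `selected` (per-length feature sets), and `oof` when kept.
#' @export
run_experiment <- function(nni_list, lengths = c(5, 10, 20, 30, 40, 50, 60),
                           models = default_models(seed = seed), k = 10,
                           seed = 1L, group_by = "none", stride = 1,
                           label_len = 60, threshold = 0.6, scaling = "l2",
                           keep_oof = TRUE) {
  grid <- matrix(NA_real_, nrow = length(models), ncol = length(lengths),
                 dimnames = list(names(models), paste0(lengths, "s")))
  fold_scores <- list()
  oof <- list()
  n_samples <- stats::setNames(integer(length(lengths)),
                               paste0(lengths, "s"))
  selected <- list()
  for (j in seq_along(lengths)) {
    L <- lengths[j]
    ds <- build_dataset(nni_list, L = L, stride = stride,
                        label_len = label_len, threshold = threshold,
                        scaling = scaling)
    n_samples[j] <- length(ds$y)
    selected[[paste0(L, "s")]] <- ds$selected_features
    for (m in names(models)) {
      cv <- cross_validate(ds, models[[m]], k = k, seed = seed,
                           group_by = group_by)
      grid[m, j] <- cv$mean_r2
      fold_scores[[paste0(m, "_", L, "s")]] <- cv$fold_scores
      if (keep_oof) oof[[paste0(m, "_", L, "s")]] <- cv$oof
    }
  }
  structure(
    list(grid = grid, mean_row = colMeans(grid), fold_scores = fold_scores,
         n_samples = n_samples, selected = selected,
         oof = if (keep_oof) oof, lengths = lengths, k = k, seed = seed,
         group_by = group_by),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, digits = 4, ...) {
  cat(sprintf("<experiment_result> mean %d-fold CV R2 (%s folds):\n",
              x$k, if (x$group_by == "none") "sample-level" else "grouped"))
  tab <- rbind(x$grid, mean = x$mean_row)
  print(round(tab, digits))
  cat("samples per length:", paste(x$n_samples, collapse = ", "), "\n")
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.74135 -> 0.7414 at 4 digits),
#' matching how summary tables are conventionally printed; base `round()`
#' rounds ties to even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Per-length average row of a model-score grid
#'
#' Averages each column (window length) of a models x lengths score grid and
#' rounds half-up to `digits` decimals, the summarisation used in the
#' published score table.
#'
#' @param grid Numeric matrix, models in rows, window lengths in columns.
#' @param digits Decimals for the rounded row (default 4); `NULL` to skip
#'   rounding.
#' @return Named numeric vector of per-length means.
#' @export
grid_mean_row <- function(grid, digits = 4) {
  m <- colMeans(as.matrix(grid))
  if (is.null(digits)) m else round_half_up(m, digits)
}

#' Preprocess a synthetic cohort into NN-interval series
#'
#' @param cohort Result of [generate_cohort()].
#' @param cfg A [preprocess_config()].
#' @return Named list of `nni_series`, names `subjectNN_state`.
#' @export
preprocess_cohort <- function(cohort, cfg = preprocess_config()) {
  out <- lapply(cohort, function(el) preprocess(el$recording, cfg))
  names(out) <- vapply(cohort, function(el) {
    paste0(el$recording$subject_id, "_", el$recording$state)
  }, character(1))
  out
}
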