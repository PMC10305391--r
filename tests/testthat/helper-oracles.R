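# Independent brute-force oracles, written with explicit loops and closed
# forms so they share no code path with the package implementation.

# All 18 time-domain features, loop by loop.
oracle_features <- function(x) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v
  m <- m / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  sdnn <- sqrt(ss / (n - 1))
  d <- numeric(n - 1)
  for (i in seq_len(n - 1)) d[i] <- x[i + 1] - x[i]
  sq <- 0
  for (v in d) sq <- sq + v^2
  rmssd <- sqrt(sq / (n - 1))
  dm <- 0
  for (v in d) dm <- dm + v
  dm <- dm / (n - 1)
  ds <- 0
  for (v in d) ds <- ds + (v - dm)^2
  sdsd <- sqrt(ds / (n - 2))
  s <- sort(x)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  n50 <- 0L
  n20 <- 0L
  for (v in d) {
    if (abs(v) > 50) n50 <- n50 + 1L
    if (abs(v) > 20) n20 <- n20 + 1L
  }
  hr <- numeric(n)
  for (i in seq_len(n)) hr[i] <- 60000 / x[i]
  hm <- 0
  for (v in hr) hm <- hm + v
  hm <- hm / n
  hs <- 0
  for (v in hr) hs <- hs + (v - hm)^2
  c(mean_nni = m, sdnn = sdnn, sdsd = sdsd, rmssd = rmssd, median_nni = med,
    nni_50 = n50, pnni_50 = n50 / n, nni_20 = n20, pnni_20 = n20 / n,
    range_nni = s[n] - s[1], cvsd = rmssd / m, cvnni = sdnn / m,
    mean_hr = hm, max_hr = max(hr), min_hr = min(hr),
    std_hr = sqrt(hs / (n - 1)), max_nni = s[n], min_nni = s[1])
}

# Baevsky SI via an explicit histogram loop over 50 ms (or w ms) bins.
oracle_si <- function(x, w = 50) {
  lo <- floor(min(x) / w)
  hi <- floor(max(x) / w)
  best_bin <- NA
  best_count <- -1L
  for (k in lo:hi) {
    cnt <- 0L
    for (v in x) if (v >= k * w && v < (k + 1) * w) cnt <- cnt + 1L
    if (cnt > best_count) {       # strict '>' keeps the lower bin on ties
      best_count <- cnt
      best_bin <- k
    }
  }
  mo <- (best_bin + 0.5) * w / 1000
  amo <- 100 * best_count / length(x)
  mxdmn <- (max(x) - min(x)) / 1000
  amo / (2 * mo * mxdmn)
}

# Random NN-interval series sampler for property tests.
random_nni <- function(n = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- sample(5:60, 1)
  stats::runif(n, 400, 1200)
}

# Memoised default-cohort NN series shared by the acceptance blocks.
.cache <- new.env(parent = emptyenv())
default_cohort_nni <- function(seed = 42) {
  key <- paste0("nni_", seed)
  if (is.null(.cache[[key]])) {
    cohort <- generate_cohort(synth_config(seed = seed))
    .cache[[key]] <- preprocess_cohort(cohort)
  }
  .cache[[key]]
}

# Ground-truth interval series wrapped as an nni_series (no waveform step),
# for dataset/model tests that do not exercise preprocessing.
truth_nni <- function(state = default_states()$rest, duration_s = 300,
                      seed = 1) {
  gt <- generate_nni_series(state, duration_s, seed = seed)
  nni_series(gt$rr_intervals, times = gt$pulse_times[-1],
             duration_s = duration_s)
}

# Minimal dataset wrapper for model-level tests.
make_dataset <- function(x, y, groups = rep("r1", length(y)), L = 60) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(samples = NULL, selection = NULL,
                 selected_features = colnames(x), x = x, y = y,
                 groups = groups, window_len = L, n_dropped = 0L),
            class = "window_dataset")
}
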