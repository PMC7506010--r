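# Shared fixtures, built in code and memoized across test files.

.fixture_cache <- new.env()

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tiny_cohort <- function() memo("tiny_cohort",
  simulate_cohort(sim_config(n_subjects = 6, reps_per_task = 2, seed = 101)))

tiny_feats <- function() memo("tiny_feats", cohort_features(tiny_cohort()))

# Minimal hand-built objects for constructor/IO tests -------------------------

make_channel <- function(placement = "wrist_affected", n = 60, n_axes = 3,
                         fs = 50, value = NULL) {
  m <- if (is.null(value)) matrix(sin(seq_len(n * n_axes) / 5), n, n_axes)
  else matrix(value, n, n_axes)
  sensor_channel(placement, m, fs)
}

make_trial <- function(task_id = "WMFT-1", repetition = 1L, n = 60) {
  channels <- list(
    make_channel("chest", n),
    make_channel("wrist_affected", n),
    make_channel("thumb_affected", n, n_axes = 2))
  sensor_trial(task_id, repetition, channels)
}

make_session <- function(subject_id = "S01", fma = 40,
                         diagnosis = "stroke", n = 60) {
  subject_session(subject_id, diagnosis, "baseline", fma,
                  fas_true_per_task = c("WMFT-1" = 3),
                  trials = list(make_trial(n = n)))
}

# Exhaustive CFS search over all nonempty subsets (oracle for best-first)
exhaustive_cfs <- function(X, y) {
  X <- as.matrix(X)
  p <- ncol(X)
  rcf <- abs(suppressWarnings(stats::cor(X, y)))
  rcf[!is.finite(rcf)] <- 0
  rff <- abs(suppressWarnings(stats::cor(X)))
  rff[!is.finite(rff)] <- 0
  diag(rff) <- 0
  best_merit <- -Inf
  best_set <- integer(0)
  for (k in seq_len(p)) {
    sets <- utils::combn(p, k)
    for (j in seq_len(ncol(sets))) {
      s <- sets[, j]
      merit <- sum(rcf[s]) / sqrt(k + sum(rff[s, s, drop = FALSE]))
      if (merit > best_merit) {
        best_merit <- merit
        best_set <- s
      }
    }
  }
  list(members = best_set, merit = best_merit)
}
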