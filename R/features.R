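## Nine feature families per trial, computed on the kinematic magnitude
## series of every placement: (1) min/max/mean, (2) RMS, (3) dominant-
## frequency power ratio, (4) jerk (RMS of the jerk magnitude), (5) skewness,
## (6) histogram entropy, (7) excess kurtosis, (8) correlation coefficients
## (inter-placement acceleration-magnitude correlations and intra-sensor
## inter-axis correlations), (9) trial duration.

series_order <- c("displacement", "velocity", "acceleration", "jerk")
stat_order <- c("min", "max", "mean", "rms", "domfreq_ratio",
                "skewness", "kurtosis", "entropy")
entropy_bins_default <- 16L

# Pearson correlation with the degenerate (constant-series) case defined as 0
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

# Ratio of the dominant periodogram peak to total power, DC bin excluded
domfreq_ratio <- function(v) {
  n <- length(v)
  p <- Mod(stats::fft(v))^2
  p <- p[2:(floor(n / 2) + 1)]            # positive frequencies, no DC
  tot <- sum(p)
  if (tot <= 0) return(0)
  max(p) / tot
}

# Shannon entropy (nats) of a 16-bin histogram of the min-max-normalized
# series; constant series have zero entropy by convention
hist_entropy <- function(v, bins = entropy_bins_default) {
  rng <- range(v)
  if (rng[2] == rng[1]) return(0)
  u <- (v - rng[1]) / (rng[2] - rng[1])
  counts <- tabulate(pmin(floor(u * bins) + 1L, bins), nbins = bins)
  p <- counts / length(v)
  p <- p[p > 0]
  -sum(p * log(p))
}

series_stats <- function(v, bins = entropy_bins_default) {
  sk <- e1071::skewness(v, type = 2)
  ku <- e1071::kurtosis(v, type = 2)
  c(min = min(v), max = max(v), mean = mean(v), rms = sqrt(mean(v^2)),
    domfreq_ratio = domfreq_ratio(v),
    skewness = if (is.finite(sk)) sk else 0,
    kurtosis = if (is.finite(ku)) ku else 0,
    entropy = hist_entropy(v, bins))
}

#' Extract the feature vector of one prepared trial
#'
#' The trial must already be segmented to its marker window and band-filtered
#' (see [segment_trial()], [filter_trial()], or the convenience wrapper
#' [trial_features()]). The output is deterministic in length and order for a
#' fixed montage: 8 statistics x 4 kinematic series per placement, pairwise
#' acceleration-magnitude correlations between all placements, intra-sensor
#' inter-axis correlations, and the trial duration in seconds.
#'
#' @param trial A segmented, band-filtered [sensor_trial].
#' @param subject_id Optional subject identifier carried in the result.
#' @param bins Histogram bins for the entropy feature.
#' @return Object of class `feature_vector`: list with `names`, `values`
#'   (finite numerics), `task_id`, `subject_id`, `repetition`.
#' @export
extract_features <- function(trial, subject_id = NA_character_,
                             bins = entropy_bins_default) {
  channels <- trial$channels[order(match(names(trial$channels),
                                         sensor_placements))]
  kin <- lapply(channels, derive_kinematics)
  vals <- c()
  for (ch_name in names(kin)) {
    k <- kin[[ch_name]]
    for (sname in series_order) {
      st <- series_stats(k[[sname]], bins)
      names(st) <- paste(ch_name, sname, names(st), sep = "_")
      vals <- c(vals, st)
    }
  }
  # inter-placement correlations of the acceleration magnitude series
  pl <- names(kin)
  if (length(pl) >= 2) {
    for (i in seq_len(length(pl) - 1)) for (j in seq.int(i + 1, length(pl))) {
      vals[paste("corr", pl[i], pl[j], sep = "_")] <-
        safe_cor(kin[[pl[i]]]$acceleration, kin[[pl[j]]]$acceleration)
    }
  }
  # intra-sensor inter-axis correlations of the filtered accelerations
  for (ch_name in names(channels)) {
    m <- channels[[ch_name]]$samples
    na <- ncol(m)
    for (i in seq_len(na - 1)) for (j in seq.int(i + 1, na)) {
      vals[paste("axcorr", ch_name, i, j, sep = "_")] <-
        safe_cor(m[, i], m[, j])
    }
  }
  n <- nrow(channels[[1]]$samples)
  vals["duration"] <- n / channels[[1]]$fs
  if (any(!is.finite(vals)))
    stop("non-finite feature values in ", trial$task_id, " rep ",
         trial$repetition, call. = FALSE)
  structure(list(names = names(vals), values = unname(vals),
                 task_id = trial$task_id, subject_id = subject_id,
                 repetition = trial$repetition),
            class = "feature_vector")
}

#' Segment, filter and featurize a raw trial
#'
#' @inheritParams extract_features
#' @return A `feature_vector`; see [extract_features()].
#' @export
trial_features <- function(trial, subject_id = NA_character_,
                           bins = entropy_bins_default) {
  extract_features(filter_trial(segment_trial(trial)), subject_id, bins)
}

#' Feature tables for a whole cohort
#'
#' Runs the full preparation chain on every trial and assembles, per WMFT
#' task, a data frame with one row per repetition: `subject_id`,
#' `repetition`, the subject labels (`fma_true`, per-task `fas_true`) and one
#' column per feature.
#'
#' @param cohort List of [subject_session] objects.
#' @param bins Histogram bins for the entropy feature.
#' @return List with `tasks` (named list of data frames), `feature_names`,
#'   and `truth` (per-subject data frame with `subject_id`, `fma_true`,
#'   `fas_total_true`).
#' @export
cohort_features <- function(cohort, bins = entropy_bins_default) {
  rows <- list()
  for (ss in cohort) {
    for (tr in ss$trials) {
      fv <- trial_features(tr, subject_id = ss$subject_id, bins = bins)
      rows[[length(rows) + 1L]] <- list(fv = fv,
                                        fma = ss$fma_true,
                                        fas = ss$fas_true_per_task[[tr$task_id]])
    }
  }
  feature_names <- rows[[1]]$fv$names
  tasks <- list()
  for (task in wmft_tasks) {
    sel <- Filter(function(r) r$fv$task_id == task, rows)
    if (!length(sel)) next
    X <- do.call(rbind, lapply(sel, function(r) r$fv$values))
    colnames(X) <- feature_names
    df <- data.frame(
      subject_id = vapply(sel, function(r) r$fv$subject_id, character(1)),
      repetition = vapply(sel, function(r) r$fv$repetition, integer(1)),
      fma_true = vapply(sel, function(r) r$fma, numeric(1)),
      fas_true = vapply(sel, function(r) r$fas, numeric(1)),
      stringsAsFactors = FALSE)
    tasks[[task]] <- cbind(df, as.data.frame(X))
  }
  truth <- data.frame(
    subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
    fma_true = vapply(cohort, `[[`, numeric(1), "fma_true"),
    fas_total_true = vapply(cohort, function(ss)
      if (all(wmft_tasks %in% names(ss$fas_true_per_task)))
        fas_total(ss$fas_true_per_task) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE)
  list(tasks = tasks, feature_names = feature_names, truth = truth)
}
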