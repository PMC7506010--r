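## Plain-text cohort serialization: one CSV per trial + one JSON manifest.
## Diffable, language-neutral, lossless to >= 9 significant digits.

#' Write a cohort to disk
#'
#' Serializes a list of [subject_session] objects as one JSON manifest plus
#' one CSV file per trial (one row per sample, one column per axis, header
#' `<placement>_<x|y|z>`). File layout and column order are deterministic.
#'
#' @param sessions List of [subject_session] objects.
#' @param path Directory to write into (created if absent).
#' @return Invisibly, the manifest path.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(sessions, path) {
  for (ss in sessions) validate_session(ss)
  dir.create(file.path(path, "trials"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path)
  manifest <- list(format = "senscore-cohort", version = 1L,
                   subjects = list())
  for (ss in sessions) {
    trials <- ss$trials[order(match(vapply(ss$trials, `[[`, "", "task_id"),
                                    wmft_tasks),
                              vapply(ss$trials, `[[`, 1L, "repetition"))]
    trial_meta <- lapply(trials, function(tr) {
      file <- file.path("trials",
                        paste0(ss$subject_id, "_", tr$task_id, "_rep",
                               tr$repetition, ".csv"))
      write_trial_csv(tr, file.path(path, file))
      list(task_id = tr$task_id, repetition = tr$repetition,
           fs = tr$channels[[1]]$fs,
           start_marker = tr$start_marker, end_marker = tr$end_marker,
           file = file)
    })
    manifest$subjects[[length(manifest$subjects) + 1L]] <- list(
      subject_id = ss$subject_id, diagnosis = ss$diagnosis,
      visit = ss$visit, fma_true = ss$fma_true,
      fas_true_per_task = as.list(ss$fas_true_per_task),
      demographics = ss$demographics,
      trials = trial_meta)
  }
  manifest_path <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(manifest_path)
}

write_trial_csv <- function(tr, file) {
  cols <- list()
  for (ch in tr$channels) {
    ax <- axis_names(ncol(ch$samples))
    for (j in seq_along(ax))
      cols[[paste0(ch$placement, "_", ax[j])]] <- ch$samples[, j]
  }
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(names(cols), collapse = ","), con)
  # %.12g keeps >= 9 significant digits through a text round trip
  body <- do.call(paste, c(lapply(cols, function(v) sprintf("%.12g", v)),
                           sep = ","))
  writeLines(body, con)
}

#' Read a cohort from disk
#'
#' Inverse of [write_cohort()]: reads the manifest and per-trial CSVs and
#' reconstructs validated [subject_session] objects. Invariant violations
#' (e.g. a thumb channel with three axes) raise errors naming the subject and
#' trial concerned.
#'
#' @param path Directory containing `manifest.json`.
#' @return List of [subject_session] objects.
#' @export
read_cohort <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path))
    stop("no manifest.json under ", path, call. = FALSE)
  manifest <- jsonlite::read_json(manifest_path)
  lapply(manifest$subjects, function(sub) {
    trials <- lapply(sub$trials, function(tm) {
      file <- file.path(path, tm$file)
      if (!file.exists(file))
        stop("missing trial file ", tm$file, " [", sub$subject_id, "]",
             call. = FALSE)
      dat <- utils::read.csv(file, check.names = FALSE,
                             colClasses = "numeric")
      tryCatch(read_trial(tm, dat, sub$subject_id),
               error = function(e)
                 stop(conditionMessage(e), " [", sub$subject_id, " ",
                      tm$task_id, " rep ", tm$repetition, "]",
                      call. = FALSE))
    })
    subject_session(
      subject_id = sub$subject_id, diagnosis = sub$diagnosis,
      visit = sub$visit, fma_true = sub$fma_true,
      fas_true_per_task = unlist(sub$fas_true_per_task),
      trials = trials,
      demographics = sub$demographics)
  })
}

read_trial <- function(tm, dat, subject_id) {
  parts <- strsplit(names(dat), "_(?=[xyz]$)", perl = TRUE)
  placements <- vapply(parts, `[[`, "", 1L)
  channels <- lapply(unique(placements), function(p) {
    m <- as.matrix(dat[placements == p])
    dimnames(m) <- NULL
    sensor_channel(p, m, fs = tm$fs)
  })
  sensor_trial(tm$task_id, tm$repetition, channels,
               start_marker = tm$start_marker, end_marker = tm$end_marker)
}
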