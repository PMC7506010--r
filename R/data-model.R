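#' @keywords internal
"_PACKAGE"

## Domain constants ----------------------------------------------------------

#' WMFT tasks used by the pipeline
#'
#' The eight Wolf Motor Function Test items the estimators operate on:
#' four arm-reaching tasks (forearm to table-side, extend elbow-side, hand to
#' table, reach and retrieve) and four manipulation tasks (lift can, lift
#' pencil, flip cards, turn key).
#'
#' @format Character vector of length 8.
#' @export
wmft_tasks <- c("WMFT-1", "WMFT-3", "WMFT-5", "WMFT-8",
                "WMFT-9", "WMFT-10", "WMFT-13", "WMFT-15")

#' Sensor placements
#'
#' Admissible accelerometer placements. Thumb and index units carry two-axis
#' accelerometers; all others three-axis.
#'
#' @format Character vector of length 7.
#' @export
sensor_placements <- c("chest", "arm_affected", "arm_unaffected",
                       "wrist_affected", "wrist_unaffected",
                       "thumb_affected", "index_affected")

two_axis_placements <- c("thumb_affected", "index_affected")

#' FMA class boundaries
#'
#' Right-closed upper edges of the first four FMA classes used for balanced
#' bootstrap sampling and per-class error analysis: class 1 is FMA <= 30,
#' class 2 is 30 < FMA <= 38, class 3 is 38 < FMA <= 47, class 4 is
#' 47 < FMA <= 56 and class 5 is FMA > 56.
#'
#' @format Integer vector of length 4.
#' @export
fma_class_edges <- c(30L, 38L, 47L, 56L)

#' Assign FMA scores to classes
#'
#' @param fma Numeric vector of FMA scores (0-66).
#' @param edges Strictly increasing upper class edges within (0, 66).
#' @return Integer vector of class labels in `1:(length(edges) + 1)`; edges
#'   are inclusive on the right, so a score of exactly 30 falls in class 1.
#' @export
#' @examples
#' fma_class(c(20, 30, 35, 40, 50, 60))
fma_class <- function(fma, edges = fma_class_edges) {
  stopifnot(is.numeric(fma), all(diff(edges) > 0))
  vapply(fma, function(y) sum(y > edges) + 1L, integer(1))
}

## Constructors ---------------------------------------------------------------

#' Construct a sensor channel
#'
#' One accelerometer unit's recording for one trial: an `n_samples x n_axes`
#' matrix of accelerations in g at sampling rate `fs`.
#'
#' @param placement One of [sensor_placements].
#' @param samples Numeric matrix, `n_samples x n_axes` (axes in columns).
#' @param fs Sampling frequency in Hz; must exceed 16 Hz (twice the 8 Hz
#'   low-pass cut-off).
#' @return Object of class `sensor_channel`.
#' @export
sensor_channel <- function(placement, samples, fs) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  ch <- structure(
    list(placement = placement, samples = samples, fs = as.numeric(fs)),
    class = "sensor_channel")
  validate_channel(ch)
  ch
}

validate_channel <- function(ch, where = "") {
  ctx <- if (nzchar(where)) paste0(" [", where, "]") else ""
  if (!ch$placement %in% sensor_placements)
    stop("unknown placement '", ch$placement, "'", ctx, call. = FALSE)
  n_axes <- ncol(ch$samples)
  expected <- if (ch$placement %in% two_axis_placements) 2L else 3L
  if (n_axes != expected)
    stop("placement '", ch$placement, "' must have ", expected,
         " axes, got ", n_axes, ctx, call. = FALSE)
  if (nrow(ch$samples) < 1L)
    stop("channel '", ch$placement, "' has no samples", ctx, call. = FALSE)
  if (!is.finite(ch$fs) || ch$fs <= 16)
    stop("fs must exceed 16 Hz (got ", ch$fs, ")", ctx, call. = FALSE)
  if (any(!is.finite(ch$samples)))
    stop("non-finite samples in channel '", ch$placement, "'", ctx,
         call. = FALSE)
  invisible(ch)
}

#' Construct a sensor trial
#'
#' One repetition of one WMFT task: a set of simultaneously recorded channels
#' plus the digital marker window `[start_marker, end_marker)` (half-open,
#' 1-based start, exclusive end) delimiting task performance.
#'
#' @param task_id One of [wmft_tasks].
#' @param repetition Integer 1-3.
#' @param channels List of [sensor_channel] objects (named by placement or
#'   unnamed).
#' @param start_marker,end_marker Sample indices of the half-open task window;
#'   defaults cover the full recording.
#' @return Object of class `sensor_trial`.
#' @export
sensor_trial <- function(task_id, repetition, channels,
                         start_marker = 1L,
                         end_marker = nrow(channels[[1]]$samples) + 1L) {
  names(channels) <- vapply(channels, function(ch) ch$placement, character(1))
  tr <- structure(
    list(task_id = task_id, repetition = as.integer(repetition),
         channels = channels,
         start_marker = as.integer(start_marker),
         end_marker = as.integer(end_marker)),
    class = "sensor_trial")
  validate_trial(tr)
  tr
}

validate_trial <- function(tr, where = "") {
  ctx0 <- paste0(tr$task_id, " rep ", tr$repetition)
  ctx <- if (nzchar(where)) paste(where, ctx0) else ctx0
  if (!tr$task_id %in% wmft_tasks)
    stop("unknown task_id '", tr$task_id, "' [", ctx, "]", call. = FALSE)
  if (tr$repetition < 1L || tr$repetition > 3L)
    stop("repetition must be 1-3 [", ctx, "]", call. = FALSE)
  if (length(tr$channels) < 1L)
    stop("trial has no channels [", ctx, "]", call. = FALSE)
  for (ch in tr$channels) validate_channel(ch, where = ctx)
  fs <- vapply(tr$channels, function(ch) ch$fs, numeric(1))
  if (length(unique(fs)) != 1L)
    stop("channels disagree on fs [", ctx, "]", call. = FALSE)
  ns <- vapply(tr$channels, function(ch) nrow(ch$samples), integer(1))
  if (length(unique(ns)) != 1L)
    stop("channels disagree on length [", ctx, "]", call. = FALSE)
  if (tr$end_marker <= tr$start_marker)
    stop("end_marker must exceed start_marker [", ctx, "]", call. = FALSE)
  if (tr$start_marker < 1L || tr$end_marker > ns[1] + 1L)
    stop("marker window outside recording [", ctx, "]", call. = FALSE)
  invisible(tr)
}

#' Construct a subject session
#'
#' One subject's visit: all recorded trials plus the clinician-assigned
#' labels (FMA total and per-task FAS scores) and optional demographics.
#'
#' @param subject_id Character scalar.
#' @param diagnosis `"stroke"` or `"TBI"`.
#' @param visit `"baseline"` or `"discharge"`.
#' @param fma_true Integer FMA total in 0-66.
#' @param fas_true_per_task Named numeric vector/list, task id -> FAS in 0-5.
#' @param trials List of [sensor_trial] objects.
#' @param demographics Optional named list (age, sex, ...).
#' @return Object of class `subject_session`.
#' @export
subject_session <- function(subject_id, diagnosis, visit, fma_true,
                            fas_true_per_task, trials,
                            demographics = NULL) {
  ss <- structure(
    list(subject_id = as.character(subject_id), diagnosis = diagnosis,
         visit = visit, fma_true = as.numeric(fma_true),
         fas_true_per_task = unlist(fas_true_per_task),
         trials = trials, demographics = demographics),
    class = "subject_session")
  validate_session(ss)
  ss
}

validate_session <- function(ss) {
  id <- ss$subject_id
  if (!ss$diagnosis %in% c("stroke", "TBI"))
    stop("diagnosis must be stroke or TBI [", id, "]", call. = FALSE)
  if (!ss$visit %in% c("baseline", "discharge"))
    stop("visit must be baseline or discharge [", id, "]", call. = FALSE)
  if (!is.finite(ss$fma_true) || ss$fma_true < 0 || ss$fma_true > 66)
    stop("fma_true must be in [0, 66] [", id, "]", call. = FALSE)
  fas <- ss$fas_true_per_task
  if (is.null(names(fas)) || !all(names(fas) %in% wmft_tasks))
    stop("fas_true_per_task must be named by WMFT task [", id, "]",
         call. = FALSE)
  if (any(!is.finite(fas)) || any(fas < 0) || any(fas > 5))
    stop("fas_true_per_task values must be in [0, 5] [", id, "]",
         call. = FALSE)
  trial_tasks <- vapply(ss$trials, function(tr) tr$task_id, character(1))
  missing <- setdiff(names(fas), trial_tasks)
  if (length(missing))
    stop("tasks scored but without trials: ", paste(missing, collapse = ", "),
         " [", id, "]", call. = FALSE)
  for (tr in ss$trials) validate_trial(tr, where = id)
  invisible(ss)
}

#' @export
print.subject_session <- function(x, ...) {
  cat("<subject_session> ", x$subject_id, " (", x$diagnosis, ", ", x$visit,
      ")\n  FMA ", x$fma_true, "; ", length(x$trials), " trials over ",
      length(unique(vapply(x$trials, `[[`, "", "task_id"))), " tasks\n",
      sep = "")
  invisible(x)
}

#' @export
print.sensor_trial <- function(x, ...) {
  cat("<sensor_trial> ", x$task_id, " rep ", x$repetition, ": ",
      length(x$channels), " channels, window [", x$start_marker, ", ",
      x$end_marker, ")\n", sep = "")
  invisible(x)
}

axis_names <- function(n_axes) c("x", "y", "z")[seq_len(n_axes)]

#' Clip a score estimate to its scale range
#'
#' @param x Numeric vector.
#' @param scale `"FAS"` (range 0-5) or `"FMA"` (range 0-66).
#' @return `x` clamped to the scale range.
#' @export
clip_score <- function(x, scale = c("FMA", "FAS")) {
  scale <- match.arg(scale)
  hi <- if (scale == "FAS") 5 else 66
  pmin(pmax(x, 0), hi)
}
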