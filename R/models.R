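## FAS aggregation and the four FMA estimation methods' building blocks.
## The cross-validated orchestration lives in evaluate.R.

#' FAS total-score aggregation constants
#'
#' The linear calibration mapping the sum of the eight per-task FAS scores
#' to the 0-5 FAS total: `FAS_Total = (sum * 1.78 + 2.97) / 15`.
#'
#' @format Named list with `slope`, `intercept`, `divisor`.
#' @export
fas_aggregation_constants <- list(slope = 1.78, intercept = 2.97,
                                  divisor = 15)

#' FAS total score from per-task scores
#'
#' Applies the calibrated linear aggregation to the sum of the per-task FAS
#' scores: `(sum(fas) * 1.78 + 2.97) / 15`, clipped to `[0, 5]`. With all
#' eight tasks at 0 this yields 0.198; with all at 5, about 4.9447.
#'
#' @param fas_per_task Numeric vector of per-task FAS scores; all eight WMFT
#'   tasks are required when the vector is named.
#' @return FAS total in `[0, 5]`.
#' @export
#' @examples
#' fas_total(rep(0, 8))    # 0.198
#' fas_total(rep(5, 8))    # ~4.9447
fas_total <- function(fas_per_task) {
  fas_per_task <- unlist(fas_per_task)
  if (!is.null(names(fas_per_task))) {
    missing <- setdiff(wmft_tasks, names(fas_per_task))
    if (length(missing))
      stop("missing per-task FAS for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    fas_per_task <- fas_per_task[wmft_tasks]
  } else if (length(fas_per_task) != 8L) {
    stop("eight per-task FAS scores required", call. = FALSE)
  }
  k <- fas_aggregation_constants
  clip_score((sum(fas_per_task) * k$slope + k$intercept) / k$divisor, "FAS")
}

#' FMA from FAS by linear regression (Method 1)
#'
#' Fits `FMA ~ FAS` by ordinary least squares on the training subjects'
#' clinician-assigned scores and evaluates the line at a sensor-derived FAS
#' estimate, clipping to `[0, 66]`.
#'
#' @param fas_train,fma_train Training subjects' true FAS totals and FMA
#'   totals.
#' @param fas_hat Sensor-derived FAS estimate(s) for the held-out
#'   subject(s).
#' @return FMA estimate(s) in `[0, 66]`.
#' @export
fma_from_fas_linreg <- function(fas_train, fma_train, fas_hat) {
  if (stats::sd(fas_train) == 0)
    stop("training FAS scores are constant; regression undefined",
         call. = FALSE)
  fit <- stats::lm(fma_train ~ fas_train)
  clip_score(unname(stats::predict(fit,
                                   newdata = data.frame(fas_train = fas_hat))),
             "FMA")
}
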