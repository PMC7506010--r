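## Synthetic labelled-cohort generator.
##
## Each trial is a sum of minimum-jerk-like velocity pulses per axis. Two
## correlated subject-level factors drive the signal, mirroring the distinct
## constructs the two clinical scales measure:
##   - impairment severity s = (66 - FMA)/66 drives trial duration and the
##     trunk-compensation coupling between chest and affected wrist;
##   - movement quality q = clamp(1 - s + N(0, fas_subject_sd), 0, 1) -- a
##     subject's quality can be better or worse than impairment severity
##     predicts -- drives tremor amplitude and movement fragmentation
##     (extra sub-movement pulses -> higher jerk), and generates the
##     per-task FAS labels through task-specific slopes/offsets plus small
##     rating noise.
## The default fas_subject_sd makes the cohort-level FMA-FAS correlation
## land near r^2 = 0.75, the empirical relation between the scales.

#' Simulation configuration
#'
#' Defines the statistical structure of a synthetic cohort. Defaults emulate
#' the study conditions: eight WMFT tasks, up to three repetitions, six
#' sensors per subject, a deliberately nonuniform FMA distribution over the
#' five balancing classes (per-class expected counts proportional to
#' 2/8/15/8/4), and impairment-driven duration, smoothness, tremor and
#' trunk-compensation effects.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param fs Sampling frequency in Hz (> 16).
#' @param fma_weights Nonnegative weights over the five FMA classes.
#' @param reps_per_task Repetitions per task, 1-3.
#' @param noise_sd White accelerometer noise SD in g.
#' @param tremor_band Tremor frequency band in Hz (inside the 0.25-8 Hz
#'   passband so tremor survives filtering).
#' @param a_duration Duration multiplier coefficient: duration scales with
#'   `1 + a_duration * s`.
#' @param a_tremor Tremor amplitude in g at zero movement quality.
#' @param a_submove Expected count of extra sub-movement pulses at zero
#'   movement quality.
#' @param a_chest Chest-channel coupling to the affected wrist at full
#'   impairment (`s = 1`).
#' @param fas_subject_sd SD of the subject-level movement-quality deviation
#'   (on the 0-1 quality scale); sets how far FAS can depart from what FMA
#'   predicts, calibrated so the cohort FMA-FAS correlation is near
#'   `r^2 = 0.75`.
#' @param motor_subject_sd SD of the subject-level pace/compensation trait
#'   deviation (on the impairment scale): how slow and trunk-compensated a
#'   subject moves is an imperfect correlate of their FMA, so the pace
#'   channel and the movement-quality channel are two independently noisy
#'   readouts of impairment that an estimator can usefully fuse.
#' @param fas_noise_sd SD of the per-task rating noise on FAS labels.
#' @param duration_jitter_sd SD of the per-trial lognormal duration jitter;
#'   sets how noisy a single trial's pace is as a readout of impairment,
#'   and thereby how much the cross-task FAS estimate stabilizes the
#'   per-task FMA forests.
#' @param seed Integer cohort seed; every subject derives an independent
#'   substream from it.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 40L, fs = 50,
                       fma_weights = c(2, 8, 15, 8, 4),
                       reps_per_task = 3L, noise_sd = 0.02,
                       tremor_band = c(4, 7),
                       a_duration = 1.0, a_tremor = 0.16,
                       a_submove = 6, a_chest = 0.8,
                       fas_subject_sd = 0.10, fas_noise_sd = 0.15,
                       motor_subject_sd = 0.04,
                       duration_jitter_sd = 0.15, seed = 1L) {
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects), fs = fs,
         fma_weights = fma_weights, reps_per_task = as.integer(reps_per_task),
         noise_sd = noise_sd, tremor_band = tremor_band,
         a_duration = a_duration, a_tremor = a_tremor,
         a_submove = a_submove, a_chest = a_chest,
         fas_subject_sd = fas_subject_sd, fas_noise_sd = fas_noise_sd,
         motor_subject_sd = motor_subject_sd,
         duration_jitter_sd = duration_jitter_sd,
         seed = as.integer(seed)),
    class = "sim_config")
  stopifnot(cfg$n_subjects >= 1, cfg$fs > 16,
            length(cfg$fma_weights) == 5, all(cfg$fma_weights >= 0),
            sum(cfg$fma_weights) > 0,
            cfg$reps_per_task >= 1, cfg$reps_per_task <= 3,
            cfg$noise_sd >= 0, length(cfg$tremor_band) == 2,
            cfg$tremor_band[1] < cfg$tremor_band[2],
            cfg$seed >= 0)
  cfg
}

# FMA class supports (integer scores), right-closed at the printed edges
fma_class_ranges <- function(edges = fma_class_edges) {
  lo <- c(0L, edges + 1L)
  hi <- c(edges, 66L)
  Map(function(a, b) a:b, lo, hi)
}

# Task templates: base duration (s) and main velocity pulses.
# Reaching tasks: one dominant transport pulse; manipulation tasks: two or
# three shorter pulses (grasp / transport / release phases).
task_templates <- local({
  tpl <- list(
    "WMFT-1"  = list(dur = 1.8, pulses = 1L, amp = 0.50),
    "WMFT-3"  = list(dur = 2.0, pulses = 1L, amp = 0.55),
    "WMFT-5"  = list(dur = 2.2, pulses = 1L, amp = 0.45),
    "WMFT-8"  = list(dur = 2.6, pulses = 2L, amp = 0.50),
    "WMFT-9"  = list(dur = 2.8, pulses = 2L, amp = 0.40),
    "WMFT-10" = list(dur = 3.0, pulses = 2L, amp = 0.35),
    "WMFT-13" = list(dur = 3.2, pulses = 3L, amp = 0.30),
    "WMFT-15" = list(dur = 3.4, pulses = 3L, amp = 0.30))
  tpl
})

# Monotone FAS map: task-specific slope/offset on the unimpaired fraction
fas_task_slope <- c(0.95, 1.00, 0.90, 0.92, 0.88, 0.93, 0.97, 0.90)
fas_task_offset <- c(0.20, 0.00, 0.35, 0.10, 0.25, 0.05, -0.10, 0.15)

# Gaussian velocity pulse and its analytic time derivative (acceleration)
pulse_accel <- function(t, amp, center, width) {
  amp * (-(t - center) / width^2) * exp(-((t - center)^2) / (2 * width^2))
}

#' Simulate one subject session
#'
#' Deterministic given `(fma_true, config, subject_seed)`; cohort generation
#' gives each subject an independent substream so cohort size changes never
#' shift earlier subjects.
#'
#' @param fma_true True FMA total, 0-66.
#' @param config A [sim_config].
#' @param subject_seed Integer seed for this subject's private RNG stream.
#' @param subject_id Subject identifier.
#' @param diagnosis `"stroke"` or `"TBI"`.
#' @return A [subject_session] with `8 * reps_per_task` trials across six
#'   sensors (chest, affected arm, both wrists, affected thumb and index).
#' @export
simulate_subject <- function(fma_true, config = sim_config(),
                             subject_seed = config$seed,
                             subject_id = "S01", diagnosis = "stroke") {
  stopifnot(fma_true >= 0, fma_true <= 66)
  rng <- new_rng(subject_seed)
  s <- (66 - fma_true) / 66
  # movement quality: correlated with, but not determined by, impairment
  ql <- min(1, max(0, (1 - s) + rng$norm(1, sd = config$fas_subject_sd)))
  # pace/compensation trait: how slow and trunk-compensated this subject
  # moves, again correlated with but not determined by impairment
  s_pace <- min(1, max(0, s + rng$norm(1, sd = config$motor_subject_sd)))
  fs <- config$fs

  fas <- numeric(length(wmft_tasks))
  names(fas) <- wmft_tasks
  trials <- list()
  for (ti in seq_along(wmft_tasks)) {
    task <- wmft_tasks[ti]
    fas[task] <- min(5, max(0,
      5 * ql * fas_task_slope[ti] + fas_task_offset[ti] +
        rng$norm(1, sd = config$fas_noise_sd)))
    for (rep in seq_len(config$reps_per_task)) {
      trials[[length(trials) + 1L]] <-
        simulate_trial(task, rep, s_pace, ql, config, rng)
    }
  }
  demographics <- list(age = round(rng$unif(1, 20, 79)),
                       sex = if (rng$unif(1) < 0.7) "male" else "female")
  subject_session(subject_id, diagnosis, visit = "baseline",
                  fma_true = fma_true, fas_true_per_task = fas,
                  trials = trials, demographics = demographics)
}

# One task repetition across the six-sensor montage; s drives duration and
# trunk compensation, movement quality ql drives tremor and fragmentation
simulate_trial <- function(task, rep, s, ql, config, rng) {
  tpl <- task_templates[[task]]
  fs <- config$fs
  pad <- 0.3                                  # rest before/after, seconds
  move_dur <- tpl$dur * (1 + config$a_duration * s) *
    exp(rng$norm(1, sd = config$duration_jitter_sd))
  n_move <- max(32L, round(move_dur * fs))
  n_pad <- round(pad * fs)
  n <- n_move + 2L * n_pad
  t <- (seq_len(n) - 1) / fs
  t0 <- n_pad / fs

  # main pulses spread over the movement, slight per-rep jitter
  centers <- t0 + move_dur * (seq_len(tpl$pulses) - 0.5) / tpl$pulses +
    rng$norm(tpl$pulses, sd = 0.03 * move_dur)
  widths <- move_dur / (tpl$pulses * 5) * exp(rng$norm(tpl$pulses, sd = 0.1))

  # fragmentation: extra corrective pulses, count grows as quality drops
  n_sub <- rng$pois(1, lambda = config$a_submove * (1 - ql))
  sub_centers <- rng$unif(n_sub, t0 + 0.1 * move_dur, t0 + 0.9 * move_dur)
  sub_widths <- widths[1] / 2.5 * exp(rng$norm(n_sub, sd = 0.1))

  base_axis <- function(axis_gain) {
    a <- numeric(n)
    for (k in seq_len(tpl$pulses))
      a <- a + pulse_accel(t, tpl$amp * axis_gain, centers[k], widths[k])
    for (k in seq_len(n_sub))
      a <- a + pulse_accel(t, 0.3 * tpl$amp * axis_gain * sign(rng$unif(1) - 0.5),
                           sub_centers[k], sub_widths[k])
    a
  }

  tremor_f <- rng$unif(1, config$tremor_band[1], config$tremor_band[2])
  tremor_amp <- config$a_tremor * (1 - ql) * (0.7 + 0.6 * rng$unif(1))
  tremor <- function(gain) {
    phase <- rng$unif(1, 0, 2 * pi)
    gain * tremor_amp * sin(2 * pi * tremor_f * t + phase)
  }
  noise <- function() rng$norm(n, sd = config$noise_sd)

  gains3 <- function(g) g * c(1, 0.6, 0.35) * exp(rng$norm(3, sd = 0.1))
  wrist_g <- gains3(1)
  wrist <- sapply(seq_len(3), function(j)
    base_axis(wrist_g[j]) + tremor(1) + noise())
  arm <- sapply(seq_len(3), function(j)
    0.6 * base_axis(gains3(1)[j]) + tremor(0.5) + noise())
  # unaffected wrist: modest support movement, no impairment effects
  wrist_un <- sapply(seq_len(3), function(j)
    0.25 * pulse_accel(t, tpl$amp * c(1, .6, .35)[j], centers[1],
                       widths[1] * 1.3) + noise())
  # chest: trunk compensation coupled to the affected wrist, plus small sway
  sway <- 0.03 * sin(2 * pi * 0.5 * t + rng$unif(1, 0, 2 * pi))
  chest <- sapply(seq_len(3), function(j)
    config$a_chest * s * 0.5 * wrist[, j] + sway * c(1, .7, .4)[j] + noise())
  # fingers: two-axis units, active mostly in manipulation tasks
  finger_gain <- if (tpl$pulses > 1L) 0.8 else 0.3
  thumb <- sapply(seq_len(2), function(j)
    finger_gain * base_axis(c(.5, .35)[j]) + tremor(1.2) + noise())
  index <- sapply(seq_len(2), function(j)
    finger_gain * base_axis(c(.55, .3)[j]) + tremor(1.2) + noise())

  channels <- list(
    sensor_channel("chest", chest, fs),
    sensor_channel("arm_affected", arm, fs),
    sensor_channel("wrist_affected", wrist, fs),
    sensor_channel("wrist_unaffected", wrist_un, fs),
    sensor_channel("thumb_affected", thumb, fs),
    sensor_channel("index_affected", index, fs))
  sensor_trial(task, rep, channels,
               start_marker = n_pad + 1L, end_marker = n_pad + n_move + 1L)
}

#' Simulate a labelled cohort
#'
#' Allocates subjects to the five FMA classes by quota (largest-remainder
#' apportionment of the class weights, emulating recruitment stratified
#' across severity levels), draws each subject's true FMA uniformly over the
#' integer scores of their class, shuffles subject order, and simulates each
#' session from a per-subject independent RNG substream.
#'
#' @param config A [sim_config].
#' @return List of [subject_session] objects of length `config$n_subjects`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 3, reps_per_task = 1))
#' vapply(cohort, `[[`, numeric(1), "fma_true")
simulate_cohort <- function(config = sim_config()) {
  rng <- new_rng(config$seed)
  ranges <- fma_class_ranges()
  classes <- rng$sample(apportion_classes(config$fma_weights,
                                          config$n_subjects),
                        config$n_subjects)
  fmas <- vapply(classes, function(cl) {
    r <- ranges[[cl]]
    r[rng$sample(length(r), 1L)]
  }, integer(1))
  diagnoses <- ifelse(rng$unif(config$n_subjects) < 16 / 37, "stroke", "TBI")
  lapply(seq_len(config$n_subjects), function(i) {
    simulate_subject(
      fmas[i], config,
      subject_seed = subject_substream_seed(config$seed, i),
      subject_id = sprintf("S%03d", i), diagnosis = diagnoses[i])
  })
}

# Largest-remainder apportionment of n subjects over the class weights;
# returns a vector of class labels of length n
apportion_classes <- function(weights, n) {
  w <- weights / sum(weights)
  quota <- w * n
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  rep(seq_along(weights), counts)
}

# Derive an independent per-subject seed below 2^31 from the cohort seed
subject_substream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1000003 + as.double(i) * 7919 + 12345) %%
               2147483647)
}

# Small closure-based RNG so simulation never touches the global stream state
# outside its own calls
new_rng <- function(seed) {
  env <- new.env()
  local_seed <- as.integer(seed %% 2147483647)
  with_stream <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(local_seed) else assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    norm = function(n, mean = 0, sd = 1) with_stream(function() stats::rnorm(n, mean, sd)),
    unif = function(n, min = 0, max = 1) with_stream(function() stats::runif(n, min, max)),
    pois = function(n, lambda) with_stream(function() stats::rpois(n, lambda)),
    sample = function(x, size, replace = FALSE, prob = NULL)
      with_stream(function() sample(x, size, replace = replace, prob = prob)))
}
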