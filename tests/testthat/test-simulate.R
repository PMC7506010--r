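test_that("simulation is deterministic and subjects use independent streams", {
  cfg <- sim_config(n_subjects = 4, reps_per_task = 1, seed = 17)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # regenerating one subject standalone from its substream reproduces it,
  # so changing cohort size never shifts earlier subjects
  s3 <- simulate_subject(a[[3]]$fma_true, cfg,
                         subject_seed = senscore:::subject_substream_seed(17, 3),
                         subject_id = a[[3]]$subject_id,
                         diagnosis = a[[3]]$diagnosis)
  expect_identical(a[[3]], s3)
})

test_that("class quota allocation matches the configured weights", {
  counts <- table(senscore:::apportion_classes(c(2, 8, 15, 8, 4), 40))
  expect_equal(as.integer(counts), c(2, 9, 16, 9, 4))
  expect_equal(sum(counts), 40)
  # degenerate distribution: all mass in the most impaired class
  cohort <- simulate_cohort(sim_config(n_subjects = 4, reps_per_task = 1,
                                       fma_weights = c(1, 0, 0, 0, 0),
                                       seed = 2))
  expect_true(all(vapply(cohort, `[[`, numeric(1), "fma_true") <= 30))
  # at larger n relative frequencies converge on the normalized weights
  cls <- senscore:::apportion_classes(c(2, 8, 15, 8, 4), 370)
  expect_equal(as.integer(table(cls)), c(20, 80, 150, 80, 40))
})

test_that("cohort size and per-subject trial counts are as configured", {
  cfg <- sim_config(n_subjects = 3, reps_per_task = 2, seed = 5)
  cohort <- simulate_cohort(cfg)
  expect_length(cohort, 3)
  for (ss in cohort) {
    expect_length(ss$trials, 8 * 2)
    expect_setequal(unique(vapply(ss$trials, `[[`, "", "task_id")),
                    wmft_tasks)
  }
})

test_that("impairment drives duration, jerk, tremor and trunk coupling", {
  cfg <- sim_config(n_subjects = 30, reps_per_task = 1, seed = 31)
  cohort <- simulate_cohort(cfg)
  fma <- vapply(cohort, `[[`, numeric(1), "fma_true")
  dur <- vapply(cohort, function(ss)
    mean(vapply(ss$trials, function(tr)
      (tr$end_marker - tr$start_marker) / tr$channels[[1]]$fs, numeric(1))),
    numeric(1))
  # wrist smoothness and chest-wrist coupling from one representative task
  jerk <- vapply(cohort, function(ss) {
    tr <- filter_trial(segment_trial(ss$trials[[4]]))
    dimensionless_jerk(derive_kinematics(tr$channels$wrist_affected))
  }, numeric(1))
  chw <- vapply(cohort, function(ss) {
    tr <- filter_trial(segment_trial(ss$trials[[4]]))
    stats::cor(derive_kinematics(tr$channels$chest)$acceleration,
               derive_kinematics(tr$channels$wrist_affected)$acceleration)
  }, numeric(1))
  expect_lt(stats::cor(fma, dur, method = "spearman"), -0.5)
  expect_lt(stats::cor(fma, jerk, method = "spearman"), -0.5)
  expect_lt(stats::cor(fma, chw, method = "spearman"), -0.5)
})

test_that("an unimpaired noise-free subject moves most smoothly", {
  cfg <- sim_config(n_subjects = 1, reps_per_task = 1, noise_sd = 0,
                    a_tremor = 0, fas_subject_sd = 0, seed = 3)
  smoothness <- function(fma) {
    ss <- simulate_subject(fma, cfg, subject_seed = 7)
    tr <- filter_trial(segment_trial(ss$trials[[1]]))
    dimensionless_jerk(derive_kinematics(tr$channels$wrist_affected))
  }
  grid <- vapply(c(66, 50, 35, 20, 5), smoothness, numeric(1))
  expect_identical(which.min(grid), 1L)
})

test_that("FAS labels track FMA at the intended cohort-level correlation", {
  cohort <- memo("cohort_corr",
                 simulate_cohort(sim_config(n_subjects = 60,
                                            reps_per_task = 1, seed = 53)))
  fma <- vapply(cohort, `[[`, numeric(1), "fma_true")
  fas <- vapply(cohort, function(ss) fas_total(ss$fas_true_per_task),
                numeric(1))
  expect_gte(stats::cor(fma, fas), 0.8)
  for (ss in cohort)
    expect_true(all(ss$fas_true_per_task >= 0 & ss$fas_true_per_task <= 5))
})
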