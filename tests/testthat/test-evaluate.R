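test_that("accuracy metrics follow their closed forms", {
  y <- c(0, 2, 4)
  m <- metrics(c(1, 2, 3), y)
  expect_equal(m$rmse, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(m$bias, 0)
  expect_equal(m$r2, 0.75, tolerance = 1e-12)
  # perfect estimates
  m2 <- metrics(y, y)
  expect_equal(m2$rmse, 0)
  expect_equal(m2$r2, 1)
  # constant offset: bias = rmse = offset
  m3 <- metrics(y + 2, y)
  expect_equal(m3$bias, 2)
  expect_equal(m3$rmse, 2)
  # constant truth: r2 undefined
  expect_true(is.na(metrics(c(1, 2), c(3, 3))$r2))
})

test_that("rmse^2 decomposes into bias^2 plus error variance", {
  set.seed(40)
  for (i in 1:20) {
    y <- runif(30, 0, 66)
    yhat <- y + rnorm(30, mean = runif(1, -3, 3), sd = runif(1, 0.5, 5))
    m <- metrics(yhat, y)
    e <- yhat - y
    expect_equal(m$rmse^2, m$bias^2 + mean((e - mean(e))^2),
                 tolerance = 1e-9)
  }
})

test_that("per-class summaries use true-score classes and type-7 quantiles", {
  truth <- c(20, 35, 40, 50, 60)
  est <- truth + c(-2, 0, 2, 1, -1)
  pc <- per_class_errors(est, truth)
  expect_identical(pc$class, 1:5)
  expect_identical(pc$n, rep(1L, 5))
  # errors [-2, 0, 2] within one class: median 0, quartiles -1 and 1
  pc2 <- per_class_errors(c(18, 25, 31), c(20, 25, 29))
  expect_equal(pc2$median[1], 0)
  expect_equal(pc2$q1[1], -1)
  expect_equal(pc2$q3[1], 1)
  expect_true(all(pc2$q1 <= pc2$median & pc2$median <= pc2$q3, na.rm = TRUE))
  # empty classes are reported, not dropped
  expect_identical(pc2$n[5], 0L)
  expect_true(is.na(pc2$median[5]))
})

test_that("paired class comparisons match the closed-form t", {
  # |errors| differing by [2,1,3,2,2]: t = 2/(0.7071/sqrt(5)) = 6.3246
  a <- c(2, 1, 3, 2, 2)
  b <- rep(0, 5)
  p <- paired_class_test(a, b)
  expect_equal(p, 2 * stats::pt(-6.324555, 4), tolerance = 1e-4)
  expect_equal(p, 0.0032, tolerance = 1e-3)
  # degenerate cases are flagged, not fabricated
  expect_true(is.na(paired_class_test(c(1, 2, 3), c(1, 2, 3))))
  expect_true(is.na(paired_class_test(c(2, 3, 4, 5), c(1, 2, 3, 4))))
  expect_true(is.na(paired_class_test(1, 1)))
})

test_that("the LOSO harness holds out one subject per fold", {
  cohort <- tiny_cohort()
  res <- loso_cv(cohort, function(train, test, seed) {
    # estimator must never see the held-out subject
    expect_false(test$subject_id %in%
                   vapply(train, `[[`, "", "subject_id"))
    mean(vapply(train, `[[`, numeric(1), "fma_true"))
  })
  expect_identical(nrow(res), length(cohort))
  expect_identical(anyDuplicated(res$subject_id), 0L)
  # a training-mean predictor cannot beat the cohort mean: r2 <= 0
  fma <- vapply(cohort, `[[`, numeric(1), "fma_true")
  expect_lte(metrics(res$value, fma)$r2, 0)
})

test_that("pipeline estimates are deterministic, complete and clipped", {
  feats <- tiny_feats()
  est1 <- memo("tiny_est", run_estimation(feats, seed = 77))
  est2 <- run_estimation(feats, seed = 77)
  expect_identical(est1, est2)
  expect_setequal(unique(est1$method),
                  c("fas_rf", "m1_linreg", "m2_rf", "m3_balanced_rf",
                    "m4_proposed"))
  # one estimate per subject per method
  for (m in unique(est1$method)) {
    df <- est1[est1$method == m, ]
    expect_setequal(df$subject_id, feats$truth$subject_id)
    expect_identical(anyDuplicated(df$subject_id), 0L)
  }
  fas <- est1$value[est1$scale == "FAS"]
  fma <- est1$value[est1$scale == "FMA"]
  expect_true(all(fas >= 0 & fas <= 5))
  expect_true(all(fma >= 0 & fma <= 66))
  rep <- eval_report(est1, feats$truth)
  for (m in names(rep$methods))
    expect_gte(rep$methods[[m]]$rmse, abs(rep$methods[[m]]$bias))
})

test_that("subjects missing a required task are excluded with a warning", {
  cohort <- tiny_cohort()
  crippled <- cohort[[1]]
  keep <- vapply(crippled$trials, function(tr) tr$task_id != "WMFT-9",
                 logical(1))
  crippled$trials <- crippled$trials[keep]
  crippled$fas_true_per_task <-
    crippled$fas_true_per_task[names(crippled$fas_true_per_task) != "WMFT-9"]
  feats <- cohort_features(c(list(crippled), cohort[2:6]))
  expect_warning(est <- run_estimation(feats, seed = 3, methods = "m2"),
                 "missing required tasks")
  expect_false(cohort[[1]]$subject_id %in% est$subject_id)
  expect_identical(attr(est, "excluded"), cohort[[1]]$subject_id)
})
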