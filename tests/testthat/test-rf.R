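test_that("forest predictions are bounded by the training targets", {
  set.seed(14)
  X <- data.frame(a = rnorm(80), b = rnorm(80))
  y <- 3 * X$a + rnorm(80)
  rf <- fit_task_rf(X, y, n_trees = 50, seed = 2)
  p <- predict(rf, data.frame(a = rnorm(40, sd = 4), b = rnorm(40)))
  expect_true(all(p >= min(y) & p <= max(y)))
  # constant target: every prediction equals it
  rfc <- fit_task_rf(X, rep(7, 80), n_trees = 20, seed = 2)
  expect_true(all(predict(rfc, X) == 7))
  expect_error(fit_task_rf(X[1, , drop = FALSE], 1), "two training rows")
  expect_error(fit_task_rf(data.frame(a = c(1, NA)), c(1, 2)), "non-finite")
})

test_that("a noise-free linear signal is recovered accurately", {
  set.seed(9)
  X <- data.frame(x = runif(200, -2, 2), z = rnorm(200))
  y <- 5 + 3 * X$x
  rf <- fit_task_rf(X, y, n_trees = 100, seed = 4)
  Xte <- data.frame(x = runif(100, -1.8, 1.8), z = rnorm(100))
  rmse <- sqrt(mean((predict(rf, Xte) - (5 + 3 * Xte$x))^2))
  expect_lt(rmse, 0.1 * stats::sd(y))
})

test_that("balanced bags draw exactly per_class_draw from every class", {
  set.seed(6)
  y <- c(runif(30, 0, 30), runif(4, 31, 38), runif(20, 39, 47),
         runif(3, 48, 56), runif(2, 57, 66))
  bags <- balanced_bootstrap(y, n_trees = 40, per_class_draw = 4, seed = 3)
  cls <- fma_class(y)
  for (bag in bags) {
    expect_identical(sum(bag), 20L)          # 4 draws x 5 classes
    per_class <- tapply(bag, cls, sum)
    expect_true(all(per_class == 4))
  }
})

test_that("a singleton class member fills its whole quota in every bag", {
  y <- c(20, 35, 36, 40, 41, 42)              # class 5 absent, class 1 single
  bags <- balanced_bootstrap(y, n_trees = 25, per_class_draw = 4, seed = 1)
  for (bag in bags) expect_identical(bag[1], 4L)
})

test_that("per-class bag shares are uniform regardless of raw frequencies", {
  set.seed(10)
  y <- c(runif(60, 0, 30), runif(5, 31, 38), runif(25, 39, 47),
         runif(6, 48, 56), runif(4, 57, 66))
  bags <- balanced_bootstrap(y, n_trees = 1000, per_class_draw = 6, seed = 8)
  cls <- fma_class(y)
  totals <- Reduce(`+`, lapply(bags, function(b) tapply(b, cls, sum)))
  p <- stats::chisq.test(totals, p = rep(1 / 5, 5))$p.value
  expect_gt(p, 0.001)
})

test_that("the default draw keeps the bag near the plain-bootstrap size", {
  y <- c(runif(36, 0, 30), runif(2, 57, 66))
  bags <- balanced_bootstrap(y, n_trees = 5, seed = 2)
  expect_identical(sum(bags[[1]]), as.integer(2 * ceiling(38 / 2)))
})

test_that("single-class targets fall back to a plain bootstrap", {
  y <- runif(20, 40, 45)
  expect_warning(bags <- balanced_bootstrap(y, n_trees = 10, seed = 5),
                 "one class")
  expect_true(all(vapply(bags, sum, integer(1)) == 20L))
})

test_that("forests are deterministic given the seed", {
  set.seed(19)
  X <- data.frame(a = rnorm(60), b = rnorm(60))
  y <- runif(60, 0, 66)
  p1 <- predict(fit_task_rf(X, y, 50, balanced = TRUE, seed = 7), X)
  p2 <- predict(fit_task_rf(X, y, 50, balanced = TRUE, seed = 7), X)
  expect_identical(p1, p2)
})
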