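# Printed cohort-comparison statistics recomputed from the published
# contingency counts and group summaries (stroke n=16 vs TBI n=21).

published_tables <- list(
  gender = rbind(stroke = c(9, 7), tbi = c(17, 4)),
  ethnicity = rbind(stroke = c(13, 2, 1), tbi = c(20, 0, 1)),
  hemiparesis = rbind(stroke = c(11, 5), tbi = c(6, 15)),
  setting = rbind(stroke = c(10, 6), tbi = c(20, 1)),
  dominance = rbind(stroke = c(6, 10), tbi = c(13, 8)))
published_chi2 <- c(gender = 2.65, ethnicity = 2.86, hemiparesis = 5.90,
                    setting = 6.35, dominance = 2.17)

published_summaries <- list(
  fma_baseline = list(list(n = 16, mean = 36.44, sd = 10.43),
                      list(n = 21, mean = 37.10, sd = 9.70)),
  fma_post = list(list(n = 16, mean = 45.69, sd = 12.92),
                  list(n = 21, mean = 51.67, sd = 11.78)),
  fas_baseline = list(list(n = 16, mean = 2.98, sd = 0.73),
                      list(n = 21, mean = 3.17, sd = 0.73)))
published_t <- c(fma_baseline = -0.20, fma_post = -1.47,
                 fas_baseline = -0.78)

test_that("chi-square statistics reproduce the published values", {
  for (nm in names(published_tables)) {
    r <- chi_square(published_tables[[nm]])
    expect_equal(round(r$statistic, 2), published_chi2[[nm]],
                 tolerance = 0.011, label = nm)
    expect_equal(r$df, (nrow(published_tables[[nm]]) - 1L) *
                   (ncol(published_tables[[nm]]) - 1L))
  }
})

test_that("chi-square equals the brute-force expected-count loop", {
  for (nm in names(published_tables)) {
    tab <- published_tables[[nm]]
    n <- sum(tab)
    stat <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + unname((tab[i, j] - e)^2 / e)
    }
    expect_equal(chi_square(tab)$statistic, stat, tolerance = 1e-12)
  }
  # perfectly proportional table
  expect_equal(chi_square(rbind(c(10, 10), c(20, 20)))$statistic, 0)
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "marginal")
  expect_error(chi_square(matrix(1, 1, 2)), "2x2")
})

test_that("pooled t statistics reproduce the published values", {
  for (nm in names(published_summaries)) {
    r <- independent_t(published_summaries[[nm]][[1]],
                       published_summaries[[nm]][[2]])
    expect_equal(round(r$statistic, 2), published_t[[nm]],
                 tolerance = 0.011, label = nm)
    expect_identical(r$df, 35)
  }
})

test_that("pooled t is antisymmetric and zero for equal means", {
  a <- list(n = 10, mean = 5, sd = 2)
  b <- list(n = 14, mean = 7, sd = 3)
  expect_equal(independent_t(a, b)$statistic,
               -independent_t(b, a)$statistic)
  expect_equal(independent_t(a, list(n = 8, mean = 5, sd = 1))$statistic, 0)
  expect_error(independent_t(list(n = 5, mean = 1, sd = 0),
                             list(n = 5, mean = 1, sd = 0)), "zero")
})

test_that("pooled t agrees with t.test on raw data", {
  set.seed(15)
  x <- rnorm(12, 10, 2)
  y <- rnorm(18, 11, 2)
  r <- independent_t(list(n = 12, mean = mean(x), sd = sd(x)),
                     list(n = 18, mean = mean(y), sd = sd(y)))
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(r$p, ref$p.value, tolerance = 1e-9)
})

test_that("Holm adjustment equals the hand-applied step-down algorithm", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.5, 0.5)), c(1, 1))
  # hand-stepped oracle on random inputs, plus the output properties
  set.seed(44)
  for (i in 1:10) {
    p <- runif(sample(2:8, 1))
    hand <- local({
      o <- order(p)
      m <- length(p)
      adj <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1)))
      out <- numeric(m)
      out[o] <- adj
      out
    })
    got <- holm_adjust(p)
    expect_equal(got, hand, tolerance = 1e-12)
    expect_true(all(got >= p))
    perm <- sample(length(p))
    expect_equal(holm_adjust(p[perm]), got[perm])
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("cohort_comparison assembles and Holm-adjusts all tests", {
  res <- cohort_comparison(published_tables, published_summaries)
  expect_identical(nrow(res), 8L)
  expect_true(all(res$p_holm >= res$p))
  expect_true(all(res$p_holm <= 1))
})
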