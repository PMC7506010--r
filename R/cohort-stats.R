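## Cohort comparison machinery: Pearson chi-square for categorical
## variables, pooled-variance Student t from group summaries for continuous
## variables, and the Holm step-down multiple-testing correction.

#' Pearson chi-square test for a contingency table
#'
#' No continuity correction; `df = (r - 1)(c - 1)`, expected counts from the
#' product of the margins.
#'
#' @param counts Matrix of nonnegative integer counts, at least 2x2, with
#'   groups in rows and categories in columns.
#' @return Named list: `statistic`, `df`, `p`.
#' @export
#' @examples
#' # gender by diagnosis: 9/7 male/female stroke, 17/4 TBI
#' chi_square(rbind(c(9, 7), c(17, 4)))
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("table must be at least 2x2", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal total", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Pooled-variance Student t test from group summaries
#'
#' Computes the independent-samples t statistic from per-group `n`, `mean`
#' and `sd` with the pooled variance estimate; `df = n1 + n2 - 2`. The sign
#' follows `mean_a - mean_b`.
#'
#' @param a,b Named lists/vectors with `n`, `mean`, `sd` for the two groups.
#' @return Named list: `statistic`, `df`, `p` (two-sided).
#' @export
#' @examples
#' # baseline FMA: stroke 36.44 +/- 10.43 (n 16) vs TBI 37.10 +/- 9.70 (n 21)
#' independent_t(list(n = 16, mean = 36.44, sd = 10.43),
#'               list(n = 21, mean = 37.10, sd = 9.70))
independent_t <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  stopifnot(a$n >= 2, b$n >= 2, a$sd >= 0, b$sd >= 0)
  if (a$sd == 0 && b$sd == 0)
    stop("both group SDs are zero", call. = FALSE)
  df <- a$n + b$n - 2
  sp <- sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df)
  t <- (a$mean - b$mean) / (sp * sqrt(1 / a$n + 1 / b$n))
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Holm step-down p-value adjustment
#'
#' Sorts ascending, multiplies the i-th smallest p by `m - i + 1`, enforces
#' monotonicity with a running maximum, caps at 1 and returns the adjusted
#' values in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, elementwise no smaller than the input.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.04))   # 0.03 0.04 0.04
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "holm")
}

#' Compare two cohort groups on categorical and continuous variables
#'
#' Runs [chi_square()] on each contingency table and [independent_t()] on
#' each pair of group summaries, then Holm-adjusts the p-values across all
#' comparisons.
#'
#' @param tables Named list of contingency-table matrices (groups in rows).
#' @param summaries Named list, each element a list of two group summaries
#'   (`n`, `mean`, `sd`), group a first.
#' @return Data frame with `variable`, `test`, `statistic`, `df`, `p`,
#'   `p_holm`.
#' @export
cohort_comparison <- function(tables = list(), summaries = list()) {
  rows <- list()
  for (nm in names(tables)) {
    r <- chi_square(tables[[nm]])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = nm, test = "chi-square", statistic = r$statistic,
      df = r$df, p = r$p, stringsAsFactors = FALSE)
  }
  for (nm in names(summaries)) {
    r <- independent_t(summaries[[nm]][[1]], summaries[[nm]][[2]])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = nm, test = "pooled t", statistic = r$statistic,
      df = r$df, p = r$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p)
  out
}
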