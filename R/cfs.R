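## Correlation-based feature selection (CFS): pick the feature subset S
## maximizing the merit
##
##   M_S = k * rcf_bar / sqrt(k + k (k - 1) * rff_bar)
##
## where k = |S|, rcf_bar is the mean absolute Pearson correlation between
## the features in S and the target, and rff_bar the mean absolute pairwise
## correlation within S. Search is best-first over subsets, stopping after a
## fixed number of consecutive non-improving expansions.

#' CFS merit of a feature subset
#'
#' @param rcf Absolute feature-target correlations of the subset members.
#' @param rff Absolute feature-feature correlation matrix of the subset
#'   (ignored for singletons).
#' @return The merit; for `k = 1` this is simply the feature-target
#'   correlation.
#' @export
cfs_merit <- function(rcf, rff = NULL) {
  k <- length(rcf)
  if (k == 0) return(0)
  sum_pairs <- if (k > 1) sum(rff[upper.tri(rff)]) else 0
  sum(rcf) / sqrt(k + 2 * sum_pairs)
}

#' Select features with CFS best-first search
#'
#' Expands the best open subset by one feature at a time, keeping the
#' highest-merit subset seen; stops after `max_stale` consecutive expansions
#' that fail to improve on it. For tractability on wide matrices the search
#' is restricted to the `max_candidates` features with the highest
#' feature-target correlation (any feature CFS could plausibly select; the
#' merit numerator of an excluded feature is dominated by every kept one).
#' Constant features (zero variance) are treated as having zero correlation
#' with everything and are never selected.
#'
#' @param X Numeric matrix or data frame of features (columns).
#' @param y Numeric target; must not be constant.
#' @param max_stale Consecutive non-improving expansions before stopping.
#' @param max_candidates Cap on the number of features entering the search.
#' @return Logical mask over the columns of `X` (the selected subset), with
#'   attribute `"merit"`. All-constant feature sets yield an empty mask with
#'   a warning.
#' @export
cfs_select <- function(X, y, max_stale = 5L, max_candidates = 60L) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(p >= 2)
  if (stats::sd(y) == 0) stop("target is constant", call. = FALSE)
  rcf <- numeric(p)
  ok <- matrixStats_sd(X) > 0
  if (!any(ok)) {
    warning("all features constant; empty selection")
    mask <- rep(FALSE, p)
    attr(mask, "merit") <- 0
    return(mask)
  }
  rcf[ok] <- abs(suppressWarnings(stats::cor(X[, ok, drop = FALSE], y)))
  rcf[!is.finite(rcf)] <- 0
  cand <- order(rcf, decreasing = TRUE)[seq_len(min(max_candidates, sum(ok)))]
  cand <- cand[rcf[cand] > 0]
  m <- length(cand)
  if (m == 0) {
    mask <- rep(FALSE, p)
    attr(mask, "merit") <- 0
    return(mask)
  }
  rcf_c <- rcf[cand]
  rff_c <- abs(suppressWarnings(stats::cor(X[, cand, drop = FALSE])))
  rff_c[!is.finite(rff_c)] <- 0
  diag(rff_c) <- 0

  # best-first search over candidate indices; nodes carry incremental sums
  # (sum of member-target correlations, sum of within-member pairs) so all
  # child merits of an expansion are computed in one vectorized step.
  # Subsets reachable by several orderings may enter the open list more than
  # once; re-expanding one is harmless (merit strictly increases along
  # improvements and the stale counter bounds total expansions), so no
  # deduplication bookkeeping is done.
  open_members <- list(integer(0))
  open_srcf <- 0
  open_spairs <- 0
  open_merit <- 0
  best_members <- integer(0)
  best_merit <- 0
  stale <- 0L
  while (length(open_merit) > 0 && stale < max_stale) {
    i <- which.max(open_merit)
    cur_members <- open_members[[i]]
    cur_srcf <- open_srcf[i]
    cur_spairs <- open_spairs[i]
    open_members[[i]] <- NULL
    open_srcf <- open_srcf[-i]
    open_spairs <- open_spairs[-i]
    open_merit <- open_merit[-i]
    k <- length(cur_members)
    candf <- setdiff(seq_len(m), cur_members)
    if (!length(candf)) next
    add_pairs <- if (k)
      colSums(rff_c[cur_members, candf, drop = FALSE]) else numeric(length(candf))
    child_srcf <- cur_srcf + rcf_c[candf]
    child_spairs <- cur_spairs + add_pairs
    child_merit <- child_srcf / sqrt((k + 1) + 2 * child_spairs)
    open_members <- c(open_members,
                      lapply(candf, function(f) c(cur_members, f)))
    open_srcf <- c(open_srcf, child_srcf)
    open_spairs <- c(open_spairs, child_spairs)
    open_merit <- c(open_merit, child_merit)
    j <- which.max(child_merit)
    if (child_merit[j] > best_merit + 1e-12) {
      best_merit <- child_merit[j]
      best_members <- c(cur_members, candf[j])
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
  }
  mask <- seq_len(p) %in% cand[best_members]
  attr(mask, "merit") <- best_merit
  mask
}

# column SDs without apply() overhead
matrixStats_sd <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(0, ncol(X)))
  mu <- colMeans(X)
  sqrt(pmax(0, (colSums(X^2) - n * mu^2) / (n - 1)))
}
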