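## Random-forest regression wrappers (ranger backend) and the class-balanced
## bootstrap. Balancing is implemented by constructing, for every tree, an
## inbag count vector that draws `per_class_draw` samples with replacement
## from each nonempty FMA class, so every tree sees the five impairment
## classes with equal weight regardless of the raw class frequencies.

#' Balanced bootstrap bags
#'
#' For each of `n_trees` trees, samples `per_class_draw` indices with
#' replacement from every nonempty class of `y` (classes per the printed FMA
#' edges), so every tree sees the classes with equal weight. Returns
#' per-tree inbag count vectors suitable for [ranger::ranger()]'s `inbag`
#' argument. Degenerates to a plain bootstrap with a warning when all
#' samples fall in one class.
#'
#' The default draw `"n-over-k"` (`ceiling(n / n_nonempty_classes)` per
#' class) keeps the bag size near the plain-bootstrap size `n`, balancing by
#' oversampling the minority classes. The alternative `"min-class"`
#' (downsampling to the smallest class) is the classical balanced-forest
#' convention, but with near-singleton classes it starves the trees of
#' samples.
#'
#' @param y Training scores (FMA points).
#' @param n_trees Number of bags to draw.
#' @param class_edges Upper class edges; see [fma_class_edges].
#' @param per_class_draw Samples drawn per class per tree: an integer,
#'   `"n-over-k"` (default) or `"min-class"`.
#' @param seed Integer seed.
#' @return List of `n_trees` integer vectors of length `length(y)`; each
#'   sums to `per_class_draw * n_nonempty_classes` with exactly
#'   `per_class_draw` draws per class.
#' @export
balanced_bootstrap <- function(y, n_trees, class_edges = fma_class_edges,
                               per_class_draw = "n-over-k", seed = 1L) {
  n <- length(y)
  cls <- fma_class(y, class_edges)
  counts <- table(cls)
  if (length(counts) < 2) {
    warning("all samples in one class; falling back to plain bootstrap")
    return(with_seed(seed, lapply(seq_len(n_trees), function(b)
      tabulate(sample.int(n, n, replace = TRUE), nbins = n))))
  }
  if (identical(per_class_draw, "min-class")) {
    per_class_draw <- min(counts)
  } else if (identical(per_class_draw, "n-over-k")) {
    per_class_draw <- ceiling(n / length(counts))
  }
  per_class_draw <- as.integer(per_class_draw)
  stopifnot(per_class_draw >= 1)
  idx_by_class <- split(seq_len(n), cls)
  with_seed(seed, lapply(seq_len(n_trees), function(b) {
    picked <- unlist(lapply(idx_by_class, function(idx)
      idx[sample.int(length(idx), per_class_draw, replace = TRUE)]))
    tabulate(picked, nbins = n)
  }))
}

#' Fit a random-forest regression on a task feature matrix
#'
#' Standard bootstrap RF regression (tree-mean predictions), or a balanced
#' RF when `balanced = TRUE`. Tree count defaults to 100 as for the per-task
#' models; the across-task aggregator uses 50.
#'
#' @param X Data frame or matrix of predictors.
#' @param y Numeric target scores.
#' @param n_trees Number of trees.
#' @param balanced Use the class-balanced bootstrap.
#' @param class_edges,per_class_draw Passed to [balanced_bootstrap()].
#' @param mtry Predictors tried per split; default `max(1, floor(p/3))`.
#' @param seed Integer seed (forests are deterministic given it).
#' @return Object of class `task_rf` wrapping the fitted ensemble; fields
#'   `oob` (out-of-bag predictions, `NA` where a row was never out of bag)
#'   and `y_range`.
#' @export
fit_task_rf <- function(X, y, n_trees = 100L, balanced = FALSE,
                        class_edges = fma_class_edges,
                        per_class_draw = "n-over-k",
                        mtry = NULL, seed = 1L) {
  X <- as.data.frame(X)
  if (nrow(X) < 2) stop("need at least two training rows", call. = FALSE)
  if (any(!is.finite(as.matrix(X))) || any(!is.finite(y)))
    stop("non-finite values in training data", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 3))
  dat <- cbind(..y.. = y, X)
  inbag <- NULL
  bag_size <- length(y)
  if (balanced) {
    inbag <- balanced_bootstrap(y, n_trees, class_edges, per_class_draw,
                                seed = seed)
    bag_size <- sum(inbag[[1]])
  }
  # balanced bags can be far smaller than n; scale the minimum node size
  # down so small bags still admit splits (regression default is 5)
  min_node <- max(1L, min(5L, bag_size %/% 3L))
  fit <- ranger::ranger(
    dependent.variable.name = "..y..", data = dat,
    num.trees = n_trees, mtry = min(mtry, ncol(X)),
    min.node.size = min_node,
    inbag = inbag, seed = seed, num.threads = 1,
    respect.unordered.factors = TRUE)
  oob <- fit$predictions
  oob[is.nan(oob)] <- NA_real_
  structure(list(fit = fit, feature_names = colnames(X),
                 y_range = range(y), oob = oob, balanced = balanced),
            class = "task_rf")
}

#' @export
predict.task_rf <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  stats::predict(object$fit, data = newdata, num.threads = 1)$predictions
}

# Run expr with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% 2147483647))
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  force(expr)
}

# Deterministic seed fan-out: combine integers into a derived seed < 2^31
hash_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 1315423911 + as.double(p) + 1) %% 2147483629
  as.integer(h)
}
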