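## Leave-one-subject-out cross-validation harness for the FAS estimator and
## the four FMA estimation methods, plus the accuracy metrics and per-class
## error analysis.
##
## Method 1: OLS of FMA on FAS fitted on training subjects, evaluated at the
##   sensor-derived FAS estimate.
## Method 2: per-task RF regressions (100 trees) whose per-task estimates are
##   aggregated by a second RF (50 trees).
## Method 3: Method 2 with the class-balanced bootstrap in every RF.
## Method 4: Method 3 with the sensor-derived FAS estimate added as an
##   aggregator input alongside the eight per-task estimates. (Appended to
##   the per-task forests as well, a subject-constant input acts as a
##   subject identifier among the training repetitions and degrades
##   generalization; the cross-task information it carries lives naturally
##   at the subject-level aggregation stage.)
##
## All fitting -- feature selection, forests, the Method-1 regression and the
## FAS estimates feeding Method 4 -- only ever uses data from subjects other
## than the one being estimated.

method_labels <- c(fas = "fas_rf", m1 = "m1_linreg", m2 = "m2_rf",
                   m3 = "m3_balanced_rf", m4 = "m4_proposed")

#' Run the estimation pipeline under leave-one-subject-out CV
#'
#' Computes, for every subject, the FAS estimate and the requested FMA
#' method estimates, each produced by models fitted exclusively on the other
#' subjects (feature selection included). Subjects lacking trials for any of
#' the eight tasks are excluded with a warning.
#'
#' @param feats A [cohort_features()] object (or a cohort, which will be
#'   featurized first).
#' @param methods Subset of `c("fas", "m1", "m2", "m3", "m4")`.
#' @param seed Integer master seed; all forests and bags derive from it.
#' @param n_trees_task,n_trees_agg Trees in the per-task and aggregator
#'   forests (100 and 50 by default).
#' @param class_edges FMA class edges for balancing.
#' @param per_class_draw Per-tree draws per class; see [balanced_bootstrap()].
#' @param balance_aggregator Also balance the aggregator forest (default on).
#' @param leaky_selection Select features once on the full cohort instead of
#'   inside each training fold. Deliberately wrong; exists to demonstrate the
#'   optimism of leaky protocols.
#' @return Data frame of score estimates: `subject_id`, `scale` (`"FAS"` or
#'   `"FMA"`), `method`, `value`, `fold_id`, plus attribute `"excluded"`
#'   (subjects dropped for missing tasks).
#' @export
run_estimation <- function(feats, methods = c("fas", "m1", "m2", "m3", "m4"),
                           seed = 1L, n_trees_task = 100L, n_trees_agg = 50L,
                           class_edges = fma_class_edges,
                           per_class_draw = "n-over-k",
                           balance_aggregator = TRUE,
                           leaky_selection = FALSE) {
  if (!inherits(feats, "list") || is.null(feats$tasks))
    feats <- cohort_features(feats)
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(setdiff(wmft_tasks, names(feats$tasks))))
    stop("cohort lacks trials for some of the eight tasks", call. = FALSE)
  truth <- feats$truth
  fnames <- feats$feature_names

  # exclude subjects without at least one trial in every task
  present <- Reduce(intersect, lapply(feats$tasks, function(td)
    unique(td$subject_id)))
  excluded <- setdiff(truth$subject_id, present)
  if (length(excluded))
    warning("excluding subjects missing required tasks: ",
            paste(excluded, collapse = ", "))
  truth <- truth[truth$subject_id %in% present, , drop = FALSE]
  subjects <- truth$subject_id
  n <- length(subjects)
  if (n < 3) stop("need at least three complete subjects", call. = FALSE)

  tds <- lapply(feats$tasks, function(td)
    td[td$subject_id %in% subjects, , drop = FALSE])

  leaky_mask <- NULL
  if (leaky_selection)
    leaky_mask <- lapply(seq_along(wmft_tasks), function(ti) {
      td <- tds[[wmft_tasks[ti]]]
      list(fas = cfs_select(td[, fnames], td$fas_true),
           fma = cfs_select(td[, fnames], td$fma_true))
    })

  pick_mask <- function(ti, X, y, kind) {
    if (leaky_selection) return(leaky_mask[[ti]][[kind]])
    cfs_select(X, y)
  }
  use_mask <- function(mask, X, y) {
    if (!any(mask)) {          # degenerate: fall back to best single feature
      rcf <- abs(suppressWarnings(stats::cor(as.matrix(X), y)))
      rcf[!is.finite(rcf)] <- 0
      mask[which.max(rcf)] <- TRUE
    }
    mask
  }

  need_fas <- any(c("fas", "m1", "m4") %in% methods)
  fas_hat <- stats::setNames(rep(NA_real_, n), subjects)

  ## Stage A: LOSO FAS estimates (per-repetition RF -> mean per task ->
  ## sum across tasks -> calibrated linear aggregation)
  if (need_fas) {
    for (si in seq_len(n)) {
      sid <- subjects[si]
      per_task <- numeric(length(wmft_tasks))
      for (ti in seq_along(wmft_tasks)) {
        td <- tds[[wmft_tasks[ti]]]
        tr <- td$subject_id != sid
        mask <- use_mask(pick_mask(ti, td[tr, fnames], td$fas_true[tr], "fas"),
                         td[tr, fnames], td$fas_true[tr])
        rf <- fit_task_rf(td[tr, fnames[mask], drop = FALSE],
                          td$fas_true[tr], n_trees = n_trees_task,
                          seed = hash_seed(seed, 1L, si, ti))
        per_task[ti] <- mean(predict(rf, td[!tr, fnames[mask], drop = FALSE]))
      }
      fas_hat[sid] <- fas_total(per_task)
    }
  }

  est <- list()
  add_est <- function(sid, scale, method, value) {
    est[[length(est) + 1L]] <<- data.frame(
      subject_id = sid, scale = scale, method = method_labels[[method]],
      value = value, fold_id = paste0("loso-", sid),
      stringsAsFactors = FALSE)
  }
  if ("fas" %in% methods)
    for (sid in subjects) add_est(sid, "FAS", "fas", fas_hat[sid])

  ## Stage B: LOSO FMA estimates
  fma_methods <- intersect(c("m2", "m3", "m4"), methods)
  if ("m1" %in% methods) {
    for (sid in subjects) {
      fit_rows <- truth$subject_id != sid
      add_est(sid, "FMA", "m1",
              fma_from_fas_linreg(truth$fas_total_true[fit_rows],
                                  truth$fma_true[fit_rows], fas_hat[sid]))
    }
  }

  if (length(fma_methods)) {
    ## Per-task LOSO estimates: every subject's per-task estimate comes from
    ## a forest trained on the other subjects. These feed both the
    ## aggregator's training matrix and its test input, so training and
    ## test inputs are identically distributed. Methods 3 and 4 share the
    ## balanced per-task stage; Method 4 differs only at the aggregator,
    ## where the sensor-derived FAS estimate joins the eight per-task
    ## estimates as a subject-level input.
    stages <- unique(c(if ("m2" %in% fma_methods) "plain",
                       if (any(c("m3", "m4") %in% fma_methods)) "balanced"))
    E <- lapply(stages, function(st)
      matrix(NA_real_, n, length(wmft_tasks),
             dimnames = list(subjects, make.names(wmft_tasks))))
    names(E) <- stages
    for (si in seq_len(n)) {
      sid <- subjects[si]
      for (ti in seq_along(wmft_tasks)) {
        td <- tds[[wmft_tasks[ti]]]
        tr <- td$subject_id != sid
        ytr <- td$fma_true[tr]
        mask <- use_mask(pick_mask(ti, td[tr, fnames], ytr, "fma"),
                         td[tr, fnames], ytr)
        Xtr <- td[tr, fnames[mask], drop = FALSE]
        Xte <- td[!tr, fnames[mask], drop = FALSE]
        for (st in stages) {
          rf <- if (st == "plain")
            fit_task_rf(Xtr, ytr, n_trees = n_trees_task,
                        seed = hash_seed(seed, 2L, si, ti))
          else
            fit_task_rf(Xtr, ytr, n_trees = n_trees_task,
                        balanced = TRUE, class_edges = class_edges,
                        per_class_draw = per_class_draw,
                        seed = hash_seed(seed, 3L, si, ti))
          # per-task estimate: mean over the held-out subject's repetitions
          E[[st]][si, ti] <- mean(predict(rf, Xte))
        }
      }
    }

    ## Aggregator per fold, trained on the training subjects' LOSO per-task
    ## estimates
    for (si in seq_len(n)) {
      sid <- subjects[si]
      tr_idx <- seq_len(n) != si
      fma_tr <- truth$fma_true[tr_idx]
      for (m in fma_methods) {
        st <- if (m == "m2") "plain" else "balanced"
        Za <- as.data.frame(E[[st]][tr_idx, , drop = FALSE])
        za <- as.data.frame(E[[st]][!tr_idx, , drop = FALSE])
        if (m == "m4") {
          Za$fas_hat <- unname(fas_hat[subjects[tr_idx]])
          za$fas_hat <- unname(fas_hat[sid])
        }
        agg <- fit_task_rf(Za, fma_tr, n_trees = n_trees_agg,
                           balanced = (m != "m2") && balance_aggregator,
                           class_edges = class_edges,
                           per_class_draw = per_class_draw,
                           seed = hash_seed(seed, 5L, si,
                                            match(m, c("m2", "m3", "m4"))))
        add_est(sid, "FMA", m, clip_score(predict(agg, za), "FMA"))
      }
    }
  }
  out <- do.call(rbind, est)
  attr(out, "excluded") <- excluded
  out
}

#' Generic leave-one-subject-out cross-validation
#'
#' Calls `estimator(train_sessions, test_session, seed)` once per subject;
#' the estimator returns a single numeric estimate for the held-out subject.
#'
#' @param cohort List of [subject_session] objects (at least 3).
#' @param estimator Function `(train, test, seed) -> numeric(1)`.
#' @param seed Integer seed, fanned out per fold.
#' @return Data frame with `subject_id`, `value`, `fold_id`.
#' @export
loso_cv <- function(cohort, estimator, seed = 1L) {
  stopifnot(length(cohort) >= 3)
  res <- lapply(seq_along(cohort), function(i) {
    data.frame(subject_id = cohort[[i]]$subject_id,
               value = estimator(cohort[-i], cohort[[i]],
                                 hash_seed(seed, i)),
               fold_id = paste0("loso-", cohort[[i]]$subject_id),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cross-validate one per-task estimation module
#'
#' Evaluates a single task's RF module under either subject-level
#' leave-one-subject-out CV or record-level k-fold CV (which places
#' repetitions of the same subject in both training and test sets, the
#' overfitting-prone protocol). Optionally with leaky feature selection
#' (selection on all rows before splitting).
#'
#' @param task_df One task's data frame from [cohort_features()]`$tasks`.
#' @param feature_names Feature column names.
#' @param target `"fma"` or `"fas"`.
#' @param cv `"loso"` or `"kfold"`.
#' @param k Folds for `cv = "kfold"`.
#' @param leaky_selection Select features once on all rows.
#' @param n_trees Trees per forest.
#' @param seed Integer seed.
#' @return Data frame with per-row `subject_id`, `truth`, `estimate`.
#' @export
eval_task_module <- function(task_df, feature_names,
                             target = c("fma", "fas"),
                             cv = c("loso", "kfold"), k = 10L,
                             leaky_selection = FALSE, n_trees = 100L,
                             seed = 1L) {
  target <- match.arg(target)
  cv <- match.arg(cv)
  y <- task_df[[paste0(target, "_true")]]
  X <- task_df[, feature_names, drop = FALSE]
  n <- nrow(task_df)
  folds <- if (cv == "loso") {
    as.integer(factor(task_df$subject_id))
  } else {
    with_seed(hash_seed(seed, 99L), sample(rep_len(seq_len(k), n)))
  }
  pre_mask <- if (leaky_selection) cfs_select(X, y) else NULL
  est <- rep(NA_real_, n)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    mask <- if (leaky_selection) pre_mask else cfs_select(X[tr, ], y[tr])
    if (!any(mask)) mask[1] <- TRUE
    rf <- fit_task_rf(X[tr, mask, drop = FALSE], y[tr], n_trees = n_trees,
                      seed = hash_seed(seed, f))
    est[!tr] <- predict(rf, X[!tr, mask, drop = FALSE])
  }
  data.frame(subject_id = task_df$subject_id, truth = y, estimate = est,
             stringsAsFactors = FALSE)
}

## Metrics --------------------------------------------------------------------

#' Accuracy metrics for paired estimates
#'
#' @param estimates,truth Paired numeric vectors.
#' @return Named list: `rmse` (root-mean-square error), `r2` (coefficient of
#'   determination, `1 - SSE/SST` about `mean(truth)`; `NA` for constant
#'   truth), `bias` (mean of `estimate - truth`).
#' @export
metrics <- function(estimates, truth) {
  stopifnot(length(estimates) == length(truth), length(truth) > 0)
  e <- estimates - truth
  sst <- sum((truth - mean(truth))^2)
  list(rmse = sqrt(mean(e^2)),
       r2 = if (sst == 0) NA_real_ else 1 - sum(e^2) / sst,
       bias = mean(e))
}

#' Per-class signed-error summary
#'
#' Groups signed errors (`estimate - truth`) by the TRUE score's class and
#' summarizes each class by its median and quartiles (linear-interpolation,
#' type-7 quantiles). Empty classes are reported with `n = 0` and `NA`
#' quantiles.
#'
#' @param estimates,truth Paired numeric vectors.
#' @param class_edges Upper class edges; see [fma_class_edges].
#' @return Data frame with `class`, `n`, `median`, `q1`, `q3`.
#' @export
per_class_errors <- function(estimates, truth,
                             class_edges = fma_class_edges) {
  cls <- fma_class(truth, class_edges)
  err <- estimates - truth
  n_class <- length(class_edges) + 1L
  out <- lapply(seq_len(n_class), function(cl) {
    e <- err[cls == cl]
    if (!length(e))
      return(data.frame(class = cl, n = 0L, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_))
    q <- stats::quantile(e, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(class = cl, n = length(e), median = q[2], q1 = q[1], q3 = q[3])
  })
  do.call(rbind, out)
}

#' Paired comparison of two methods' errors within a class
#'
#' Two-sided paired t test on the per-subject absolute errors of two methods
#' (the same subjects, in the same order). Returns `NA` when fewer than two
#' pairs are available or the differences have zero variance.
#'
#' @param errors_a,errors_b Signed errors of the two methods for the same
#'   subjects.
#' @param absolute Compare absolute errors (default) or signed errors.
#' @return p-value, or `NA_real_` when degenerate.
#' @export
paired_class_test <- function(errors_a, errors_b, absolute = TRUE) {
  stopifnot(length(errors_a) == length(errors_b))
  if (length(errors_a) < 2) return(NA_real_)
  a <- if (absolute) abs(errors_a) else errors_a
  b <- if (absolute) abs(errors_b) else errors_b
  d <- a - b
  if (stats::sd(d) == 0) return(NA_real_)
  stats::t.test(a, b, paired = TRUE)$p.value
}

#' Build an evaluation report from pipeline estimates
#'
#' @param estimates Output of [run_estimation()].
#' @param truth Per-subject truth (`subject_id`, `fma_true`,
#'   `fas_total_true`), e.g. [cohort_features()]`$truth`.
#' @param class_edges Upper class edges for the per-class analysis.
#' @param compare Character 2-vector of FMA method labels for the per-class
#'   paired tests (default: plain RF vs the proposed technique).
#' @return List of class `eval_report`: per-method `rmse`/`r2`/`bias`,
#'   per-class error tables for the FMA methods, and per-class paired-test
#'   p-values for the `compare` pair.
#' @export
eval_report <- function(estimates, truth, class_edges = fma_class_edges,
                        compare = c("m2_rf", "m4_proposed")) {
  by_method <- split(estimates, estimates$method)
  summaries <- lapply(by_method, function(df) {
    tru <- if (df$scale[1] == "FAS")
      truth$fas_total_true[match(df$subject_id, truth$subject_id)]
    else truth$fma_true[match(df$subject_id, truth$subject_id)]
    out <- metrics(df$value, tru)
    if (df$scale[1] == "FMA")
      out$per_class <- per_class_errors(df$value, tru, class_edges)
    out
  })
  paired <- NULL
  if (all(compare %in% names(by_method))) {
    a <- by_method[[compare[1]]]
    b <- by_method[[compare[2]]]
    b <- b[match(a$subject_id, b$subject_id), ]
    tru <- truth$fma_true[match(a$subject_id, truth$subject_id)]
    cls <- fma_class(tru, class_edges)
    paired <- data.frame(
      class = sort(unique(cls)),
      p = vapply(sort(unique(cls)), function(cl)
        paired_class_test(a$value[cls == cl] - tru[cls == cl],
                          b$value[cls == cl] - tru[cls == cl]),
        numeric(1)))
  }
  structure(list(methods = summaries, paired_tests = paired,
                 compare = compare, class_edges = class_edges),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  for (m in names(x$methods)) {
    s <- x$methods[[m]]
    cat(sprintf("  %-16s RMSE %6.3f  r2 %6.3f  bias %+6.3f\n",
                m, s$rmse, s$r2, s$bias))
  }
  if (!is.null(x$paired_tests)) {
    cat("  per-class |error| paired t (", x$compare[1], " vs ",
        x$compare[2], "):\n", sep = "")
    print(x$paired_tests, row.names = FALSE)
  }
  invisible(x)
}
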