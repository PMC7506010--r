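## Run configuration, YAML loading, provenance and the command-line entry
## point. Defaults equal the pipeline's published constants (8/0.25 Hz
## sixth-order filters, 16 entropy bins, 100/50 trees, class edges
## 30/38/47/56); every override is logged to stderr and recorded in the
## provenance JSON written alongside each run's artifacts.

#' Default run configuration
#'
#' @param seed Master seed; fans out to named substreams so simulation,
#'   bagging and cross-validation are independently reproducible.
#' @param lp_hz,hp_hz,filter_order Band-filter parameters (Hz, Hz, order).
#' @param entropy_bins Histogram bins for the entropy feature.
#' @param n_trees_task,n_trees_agg Trees in per-task and aggregator forests.
#' @param class_edges FMA class edges for balancing and error analysis.
#' @param balance_aggregator Balance the aggregator forest too.
#' @param cv `"loso"` or `"kfold:<k>"`.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, lp_hz = 8, hp_hz = 0.25, filter_order = 6L,
                       entropy_bins = 16L, n_trees_task = 100L,
                       n_trees_agg = 50L, class_edges = fma_class_edges,
                       balance_aggregator = TRUE, cv = "loso") {
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Unknown keys raise an error; every value differing from the default is
#' logged to stderr.
#'
#' @param path YAML file; `NULL` yields the defaults.
#' @return A [run_config()] list.
#' @export
load_config <- function(path = NULL) {
  cfg <- run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(user)) {
    if (!identical(unname(cfg[[k]]), unname(user[[k]]))) {
      message("config override: ", k, " = ",
              paste(user[[k]], collapse = ","))
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

write_provenance <- function(dir, command, cfg, overrides = list()) {
  tf <- tempfile()
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  prov <- list(command = command,
               config = unclass(cfg),
               config_md5 = unname(tools::md5sum(tf)),
               overrides = overrides,
               seed = cfg$seed,
               r_version = as.character(getRversion()),
               package_version = as.character(
                 utils::packageVersion("senscore")))
  unlink(tf)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prov)
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `extract`, `train`, `estimate`,
#' `evaluate` and `cohortstats` (see the `exec/senscore` script). Every run
#' writes a `provenance.json` (config hash, versions, seed) next to its
#' artifacts. Deterministic given `--seed`.
#'
#' @param args Character vector, `c(command, flags...)`.
#' @return Exit status (0 on success), invisibly.
#' @export
senscore_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: senscore <simulate|extract|train|estimate|evaluate|",
            "cohortstats> [--flags]")
    return(invisible(1L))
  }
  command <- args[1]
  opt <- parse_cli_args(args[-1])
  cfg <- load_config(opt$config)
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  out_dir <- opt$out %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  status <- tryCatch({
    switch(command,
      simulate = {
        sc <- sim_config(n_subjects = as.integer(opt$n %||% 40L),
                         seed = cfg$seed)
        write_cohort(simulate_cohort(sc), out_dir)
      },
      extract = {
        feats <- cohort_features(read_cohort(opt$cohort),
                                 bins = cfg$entropy_bins)
        for (task in names(feats$tasks))
          utils::write.csv(feats$tasks[[task]],
                           file.path(out_dir, paste0("features_", task,
                                                     ".csv")),
                           row.names = FALSE)
        utils::write.csv(feats$truth, file.path(out_dir, "truth.csv"),
                         row.names = FALSE)
      },
      train = {
        bundle <- train_models(read_cohort(opt$cohort), cfg)
        saveRDS(bundle, file.path(out_dir, "models.rds"))
        jsonlite::write_json(bundle$meta,
                             file.path(out_dir, "models.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      estimate = {
        bundle <- readRDS(file.path(opt$models, "models.rds"))
        est <- estimate_with_models(bundle, read_cohort(opt$cohort))
        utils::write.csv(est, file.path(out_dir, "estimates.csv"),
                         row.names = FALSE)
      },
      evaluate = {
        cohort <- read_cohort(opt$cohort)
        feats <- cohort_features(cohort, bins = cfg$entropy_bins)
        est <- run_estimation(feats, seed = cfg$seed,
                              n_trees_task = cfg$n_trees_task,
                              n_trees_agg = cfg$n_trees_agg,
                              class_edges = cfg$class_edges,
                              balance_aggregator = cfg$balance_aggregator)
        rep <- eval_report(est, feats$truth, class_edges = cfg$class_edges)
        utils::write.csv(est, file.path(out_dir, "estimates.csv"),
                         row.names = FALSE)
        jsonlite::write_json(
          lapply(rep$methods, function(s)
            list(rmse = s$rmse, r2 = s$r2, bias = s$bias)),
          file.path(out_dir, "metrics.json"),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      cohortstats = {
        res <- cohortstats_from_csv(opt$demographics)
        utils::write.csv(res, file.path(out_dir, "cohort_stats.csv"),
                         row.names = FALSE)
      },
      stop("unknown command: ", command, call. = FALSE))
    write_provenance(out_dir, command, cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group comparison from a demographics CSV
#'
#' Expects a `group` column; character columns become contingency tables
#' (chi-square), numeric columns become group summaries (pooled t), and all
#' p-values are Holm-adjusted together.
#'
#' @param path CSV file path.
#' @return Data frame as from [cohort_comparison()].
#' @export
cohortstats_from_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"group" %in% names(df)) stop("need a 'group' column", call. = FALSE)
  groups <- unique(df$group)
  if (length(groups) != 2) stop("need exactly two groups", call. = FALSE)
  tables <- list()
  summaries <- list()
  for (v in setdiff(names(df), "group")) {
    if (is.numeric(df[[v]])) {
      summaries[[v]] <- lapply(groups, function(g) {
        x <- df[[v]][df$group == g]
        list(n = length(x), mean = mean(x), sd = stats::sd(x))
      })
    } else {
      tables[[v]] <- as.matrix(table(df$group, df[[v]]))
    }
  }
  cohort_comparison(tables, summaries)
}

#' Fit the full model bundle on a cohort (no cross-validation)
#'
#' Fits the FAS per-task forests and the Method 4 (balanced RF + FAS input)
#' per-task and aggregator forests on all subjects, for later application to
#' new sessions via [estimate_with_models()]. FAS inputs for the FMA stage
#' use leave-one-subject-out estimates so the aggregator is trained on
#' honestly-noisy inputs.
#'
#' @param cohort List of [subject_session] objects.
#' @param cfg A [run_config()].
#' @return List with per-task models, aggregator, selection masks and
#'   metadata.
#' @export
train_models <- function(cohort, cfg = run_config()) {
  feats <- cohort_features(cohort, bins = cfg$entropy_bins)
  est <- run_estimation(feats, methods = c("fas"), seed = cfg$seed,
                        n_trees_task = cfg$n_trees_task)
  fas_hat <- stats::setNames(est$value, est$subject_id)
  fnames <- feats$feature_names
  tasks <- list()
  for (ti in seq_along(wmft_tasks)) {
    td <- feats$tasks[[wmft_tasks[ti]]]
    fas_mask <- cfs_select(td[, fnames], td$fas_true)
    fma_mask <- cfs_select(td[, fnames], td$fma_true)
    if (!any(fas_mask)) fas_mask[1] <- TRUE
    if (!any(fma_mask)) fma_mask[1] <- TRUE
    tasks[[wmft_tasks[ti]]] <- list(
      fas_mask = fas_mask, fma_mask = fma_mask,
      fas_rf = fit_task_rf(td[, fnames[fas_mask], drop = FALSE],
                           td$fas_true, n_trees = cfg$n_trees_task,
                           seed = hash_seed(cfg$seed, 11L, ti)),
      fma_rf = fit_task_rf(td[, fnames[fma_mask], drop = FALSE],
                           td$fma_true, n_trees = cfg$n_trees_task,
                           balanced = TRUE, class_edges = cfg$class_edges,
                           seed = hash_seed(cfg$seed, 12L, ti)))
  }
  oob_z <- sapply(wmft_tasks, function(task) {
    oob <- tasks[[task]]$fma_rf$oob
    td <- feats$tasks[[task]]
    m <- tapply(oob, td$subject_id, mean, na.rm = TRUE)
    as.numeric(m[feats$truth$subject_id])
  })
  Za <- as.data.frame(oob_z)
  colnames(Za) <- make.names(wmft_tasks)
  Za$fas_hat <- unname(fas_hat[feats$truth$subject_id])
  agg <- fit_task_rf(Za, feats$truth$fma_true, n_trees = cfg$n_trees_agg,
                     balanced = cfg$balance_aggregator,
                     class_edges = cfg$class_edges,
                     seed = hash_seed(cfg$seed, 13L))
  list(tasks = tasks, aggregator = agg, feature_names = fnames,
       meta = list(seed = cfg$seed, n_subjects = nrow(feats$truth),
                   method = "m4_proposed",
                   package_version = as.character(
                     utils::packageVersion("senscore"))))
}

#' Apply a trained model bundle to new sessions
#'
#' @param bundle Output of [train_models()].
#' @param cohort List of [subject_session] objects to score.
#' @return Data frame of FAS and FMA (proposed-technique) estimates.
#' @export
estimate_with_models <- function(bundle, cohort) {
  feats <- cohort_features(cohort)
  fnames <- bundle$feature_names
  out <- list()
  for (ss in cohort) {
    per_task_fas <- per_task_fma <- numeric(length(wmft_tasks))
    for (ti in seq_along(wmft_tasks)) {
      task <- wmft_tasks[ti]
      td <- feats$tasks[[task]]
      rows <- td[td$subject_id == ss$subject_id, , drop = FALSE]
      mdl <- bundle$tasks[[task]]
      per_task_fas[ti] <- mean(predict(
        mdl$fas_rf, rows[, fnames[mdl$fas_mask], drop = FALSE]))
    }
    fas_hat <- fas_total(per_task_fas)
    for (ti in seq_along(wmft_tasks)) {
      task <- wmft_tasks[ti]
      td <- feats$tasks[[task]]
      rows <- td[td$subject_id == ss$subject_id, , drop = FALSE]
      mdl <- bundle$tasks[[task]]
      per_task_fma[ti] <- mean(predict(
        mdl$fma_rf, rows[, fnames[mdl$fma_mask], drop = FALSE]))
    }
    za <- as.data.frame(as.list(stats::setNames(per_task_fma,
                                                make.names(wmft_tasks))))
    colnames(za) <- make.names(wmft_tasks)
    za$fas_hat <- fas_hat
    out[[length(out) + 1L]] <- data.frame(
      subject_id = ss$subject_id, fas_estimate = fas_hat,
      fma_estimate = clip_score(predict(bundle$aggregator, za), "FMA"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
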