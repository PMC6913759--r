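#' Pipeline configuration
#'
#' Validates and freezes every tunable of the end-to-end experiment. One
#' master `seed` governs all stochastic stages through deterministically
#' derived child seeds, so a config reproduces a run exactly.
#'
#' @param min_records Records required in each window for inclusion
#'   (default 5).
#' @param k Cross-validation folds (default 5).
#' @param n_subsamples Under-sampling repetitions per fold; must be odd so
#'   majority voting cannot tie (default 5).
#' @param families Model families to run; any of `"rf"`, `"logreg_ridge"`,
#'   `"logreg_lasso"`.
#' @param n_trees Trees per random forest classifier (default 100).
#' @param n_init k-means restarts for thresholding (default 25).
#' @param feature_sets Which feature sets to evaluate: a character vector
#'   drawn from `"all"` (the full 132) and `"consensus"` (the features
#'   surviving [consensus_select()]), and/or a named list whose elements
#'   are explicit feature-name vectors.
#' @param selection Named list of [consensus_select()] settings
#'   (`top_gini`, `top_ig`, `n_trees`, `boruta_max_iter`, `alpha`).
#' @param seed Master integer seed.
#' @return A validated `pv_config` list.
#' @export
pv_config <- function(min_records = 5L, k = 5L, n_subsamples = 5L,
                      families = c("rf", "logreg_ridge", "logreg_lasso"),
                      n_trees = 100L, n_init = 25L,
                      feature_sets = c("all", "consensus"),
                      selection = list(), seed = 1L) {
  min_records <- assert_count(min_records, "min_records", min = 2L)
  k <- assert_count(k, "k", min = 2L)
  n_subsamples <- assert_count(n_subsamples, "n_subsamples")
  if (n_subsamples %% 2L == 0L) {
    abort("`n_subsamples` must be odd so that majority voting cannot tie.",
          class = "painvol_config_error")
  }
  known <- c("rf", "logreg_ridge", "logreg_lasso")
  if (length(families) == 0L || !all(families %in% known)) {
    abort(paste0("`families` must be drawn from: ",
                 paste(known, collapse = ", ")),
          class = "painvol_config_error")
  }
  n_trees <- assert_count(n_trees, "n_trees")
  n_init <- assert_count(n_init, "n_init")
  sel_defaults <- list(top_gini = 11L, top_ig = 8L, n_trees = 50L,
                       boruta_n_trees = 30L, boruta_max_iter = 20L,
                       alpha = 0.05)
  unknown_sel <- setdiff(names(selection), names(sel_defaults))
  if (length(unknown_sel) > 0L) {
    abort(paste0("Unknown selection setting(s): ",
                 paste(unknown_sel, collapse = ", ")),
          class = "painvol_config_error")
  }
  selection <- utils::modifyList(sel_defaults, selection)
  fsets <- normalize_feature_sets(feature_sets)
  seed <- assert_count(seed, "seed", min = 0L)
  structure(
    list(min_records = min_records, k = k, n_subsamples = n_subsamples,
         families = unique(families), n_trees = n_trees, n_init = n_init,
         feature_sets = fsets, selection = selection, seed = seed),
    class = "pv_config")
}

normalize_feature_sets <- function(feature_sets) {
  if (is.character(feature_sets)) {
    bad <- setdiff(feature_sets, c("all", "consensus"))
    if (length(bad) > 0L) {
      abort(paste0("Unknown feature set keyword(s): ",
                   paste(bad, collapse = ", "),
                   " (use \"all\", \"consensus\" or a named list)."),
            class = "painvol_config_error")
    }
    return(stats::setNames(as.list(feature_sets), feature_sets))
  }
  if (is.list(feature_sets)) {
    if (is.null(names(feature_sets)) || any(names(feature_sets) == "")) {
      abort("A `feature_sets` list must be fully named.",
            class = "painvol_config_error")
    }
    return(feature_sets)
  }
  abort("`feature_sets` must be a character vector or a named list.",
        class = "painvol_config_error")
}

#' Run the full volatility-prediction experiment
#'
#' Executes the complete procedure on a cohort: inclusion filtering,
#' per-window volatility, k-means class thresholding (one threshold from
#' the pooled values of both windows; an analogous threshold on mean
#' severity feeds the severity-level feature), 132-feature extraction from
#' the predictor window, stratified k-fold splitting on the outcome class,
#' repeated random under-sampling into `k * n_subsamples` balanced training
#' sets, optional consensus feature selection, model training per training
#' set, held-out prediction of every eligible user, and majority-vote
#' consolidation across subsamples.
#'
#' Per-subsample accuracy pools, for one subsample id, the `k` fold models'
#' predictions of their own (untouched, imbalanced) test folds, so the
#' reported denominators are the full class sizes.
#'
#' @param cohort A `pv_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param config A [pv_config()].
#' @return A `pv_experiment` object; see [tidy.pv_experiment()] for the
#'   results table.
#' @export
run_experiment <- function(cohort, config = pv_config()) {
  if (!inherits(config, "pv_config")) {
    abort("`config` must come from pv_config().",
          class = "painvol_config_error")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)),
            class = "painvol_stage_error", parent = e)
    })
  }
  seeds <- derive_seeds(config$seed, 6L)

  records <- stage("windows", assign_windows(cohort$records))
  eligible <- stage("filter", filter_users(records, config$min_records))
  if (nrow(eligible) == 0L) {
    abort("[stage filter] No user passes the inclusion filter.",
          class = "painvol_stage_error")
  }

  vol <- stage("volatility",
               filter(window_volatility(records),
                      .data$user_id %in% eligible$user_id))
  labeling <- stage("threshold",
                    label_volatility(vol, seed = seeds[1L],
                                     n_init = config$n_init))

  sev <- stage("severity_level", {
    records |>
      filter(!is.na(.data$window), .data$user_id %in% eligible$user_id) |>
      group_by(.data$user_id, .data$window) |>
      summarise(m = mean(.data$severity), .groups = "drop")
  })
  severity_threshold <- stage("severity_level",
    kmeans_threshold(sev$m, seed = seeds[2L],
                     n_init = config$n_init)$threshold)

  feats <- stage("features",
    extract_features(records, cohort$profiles, users = eligible$user_id,
                     window = "predictor",
                     volatility_threshold = labeling$threshold,
                     severity_threshold = severity_threshold))

  outcome <- labeling$assignments |>
    filter(.data$window == "outcome") |>
    select("user_id", "class") |>
    mutate(class = as.character(.data$class))

  folds <- stage("folds",
                 stratified_kfold(outcome, k = config$k, seed = seeds[3L]))
  grid <- stage("grid",
                build_training_grid(folds, config$n_subsamples,
                                    seed = seeds[4L]))
  if (!check_no_leakage(grid, folds)) {
    abort("[stage grid] Leakage detected: a training set overlaps its test fold.",
          class = "painvol_stage_error")
  }

  consensus <- NULL
  if (any(vapply(config$feature_sets, identical, logical(1), "consensus"))) {
    sel <- config$selection
    consensus <- stage("selection",
      consensus_select(feats, outcome, grid,
                       top_gini = sel$top_gini, top_ig = sel$top_ig,
                       n_trees = sel$n_trees,
                       boruta_n_trees = sel$boruta_n_trees,
                       boruta_max_iter = sel$boruta_max_iter,
                       alpha = sel$alpha, seed = seeds[5L]))
  }

  all_features <- setdiff(names(feats), "user_id")
  resolve_set <- function(fs) {
    if (identical(fs, "all")) return(all_features)
    if (identical(fs, "consensus")) return(consensus$selected)
    unknown <- setdiff(fs, all_features)
    if (length(unknown) > 0L) {
      abort(paste0("Unknown feature(s) in feature set: ",
                   paste(head(unknown, 5L), collapse = ", ")),
            class = "painvol_config_error")
    }
    fs
  }

  n_models <- length(config$feature_sets) * length(config$families) *
    nrow(grid)
  model_seeds <- derive_seeds(seeds[6L], n_models)
  seed_i <- 0L

  pred_rows <- list()
  result_rows <- list()
  for (set_name in names(config$feature_sets)) {
    fset <- resolve_set(config$feature_sets[[set_name]])
    for (family in config$families) {
      votes <- matrix(NA_character_, nrow = nrow(outcome),
                      ncol = config$n_subsamples)
      for (i in seq_len(nrow(grid))) {
        seed_i <- seed_i + 1L
        train_ids <- grid$users[[i]]
        tr_idx <- match(train_ids, feats$user_id)
        x_tr <- feats[tr_idx, fset]
        y_tr <- outcome$class[match(train_ids, outcome$user_id)]
        model <- stage("models", switch(
          family,
          rf = train_rf(x_tr, y_tr, n_trees = config$n_trees,
                        seed = model_seeds[seed_i]),
          logreg_ridge = train_logreg(x_tr, y_tr, penalty = "ridge",
                                      seed = model_seeds[seed_i]),
          logreg_lasso = train_logreg(x_tr, y_tr, penalty = "lasso",
                                      seed = model_seeds[seed_i])))
        test_ids <- folds$user_id[folds$fold == grid$fold[i]]
        te_idx <- match(test_ids, feats$user_id)
        pred <- stage("predict",
                      predict(model, feats[te_idx, fset]))
        votes[match(test_ids, outcome$user_id), grid$subsample[i]] <-
          as.character(pred$.pred_class)
      }
      consolidated <- majority_vote(votes)
      for (s in seq_len(config$n_subsamples)) {
        result_rows[[length(result_rows) + 1L]] <-
          score(votes[, s], outcome$class) |>
          mutate(feature_set = set_name, family = family,
                 subsample = as.character(s))
      }
      result_rows[[length(result_rows) + 1L]] <-
        score(consolidated, outcome$class) |>
        mutate(feature_set = set_name, family = family,
               subsample = "consolidated")
      pred_rows[[length(pred_rows) + 1L]] <-
        as_tibble(stats::setNames(as.data.frame(votes),
                                  paste0("subsample_", seq_len(ncol(votes))))) |>
        mutate(user_id = outcome$user_id,
               consolidated = as.character(consolidated),
               feature_set = set_name, family = family,
               .before = 1L)
    }
  }

  results <- dplyr::bind_rows(result_rows) |>
    select("feature_set", "family", "subsample", "class", "n", "correct",
           "accuracy")
  structure(
    list(results = results,
         predictions = dplyr::bind_rows(pred_rows),
         labeling = labeling,
         severity_threshold = severity_threshold,
         consensus = consensus,
         eligible = eligible,
         outcome = outcome,
         folds = folds,
         grid = grid,
         config = config),
    class = "pv_experiment")
}

#' @export
print.pv_experiment <- function(x, ...) {
  cat(sprintf(
    "<pv_experiment> %d users (%d low / %d high); threshold %.3f\n",
    nrow(x$outcome), sum(x$outcome$class == "low"),
    sum(x$outcome$class == "high"), x$labeling$threshold))
  overall <- x$results |>
    filter(.data$class == "overall", .data$subsample == "consolidated")
  for (i in seq_len(nrow(overall))) {
    cat(sprintf("  %-10s %-13s consolidated overall: %d/%d (%.1f%%)\n",
                overall$feature_set[i], overall$family[i],
                overall$correct[i], overall$n[i],
                100 * overall$accuracy[i]))
  }
  invisible(x)
}

#' Tidy an experiment's accuracy table
#'
#' One row per feature set, model family, subsample (or
#' `"consolidated"`) and class (`"low"`, `"high"`, `"overall"`), with raw
#' correct counts, denominators and accuracies — the layout of the
#' per-subsample accuracy tables the pipeline is built to emit.
#'
#' @param x A `pv_experiment`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pv_experiment <- function(x, ...) x$results

#' @export
glance.pv_experiment <- function(x, ...) {
  x$results |>
    filter(.data$subsample == "consolidated", .data$class == "overall") |>
    select("feature_set", "family", "accuracy") |>
    tidyr::pivot_wider(names_from = "family", values_from = "accuracy") |>
    mutate(threshold = x$labeling$threshold,
           n_users = nrow(x$outcome),
           n_selected = if (is.null(x$consensus)) NA_integer_
                        else length(x$consensus$selected))
}

#' Simulate a cohort and run the experiment end-to-end
#'
#' Convenience wrapper: [simulate_cohort()] then [run_experiment()], with
#' optional writing of the cohort files, the per-user labeling, the results
#' table and a JSON run report to an output directory.
#'
#' @param params A [sim_params()]; its seed governs the cohort, while
#'   `config$seed` governs the analysis.
#' @param config A [pv_config()].
#' @param out_dir Optional directory; when given, writes `profiles.csv`,
#'   `records.csv`, `labeling.csv`, `results.csv` and `report.json` there.
#' @return The `pv_experiment`, invisibly when `out_dir` is used.
#' @export
run_pipeline <- function(params = sim_params(), config = pv_config(),
                         out_dir = NULL) {
  cohort <- simulate_cohort(params)
  exp <- run_experiment(cohort, config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_cohort(cohort, out_dir)
    readr::write_csv(tidy(exp$labeling), file.path(out_dir, "labeling.csv"))
    readr::write_csv(exp$results, file.path(out_dir, "results.csv"))
    report <- list(
      threshold = exp$labeling$threshold,
      severity_threshold = exp$severity_threshold,
      n_users = nrow(exp$outcome),
      class_sizes = as.list(table(exp$outcome$class)),
      selected_features = if (is.null(exp$consensus)) NULL
                          else exp$consensus$selected,
      config = unclass(config),
      sim_params = unclass(params))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(exp))
  }
  exp
}
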