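#' Read and write insole force traces as delimited text
#'
#' Traces are CSV files with columns `time_s`, `force_fore_N`,
#' `force_aft_N` and optionally `force_total_N` (computed as the sensor sum
#' when absent). Reading validates the grid: uniform, strictly increasing
#' time stamps (at most 1e-6 s jitter), nonnegative forces, and a total equal
#' to fore + aft; violations raise errors naming the offending rows.
#'
#' @param path File path.
#'
#' @return `read_trace()`: a validated trace tibble. `write_trace()`:
#'   `path`, invisibly.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    stop("No such trace file: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path)
  need <- c("time_s", "force_fore_N", "force_aft_N")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("Trace file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"force_total_N" %in% names(df)) {
    df$force_total_N <- df$force_fore_N + df$force_aft_N
  }
  trace <- tibble::as_tibble(df[trace_columns()])
  validate_trace(trace)
  trace
}

#' @rdname read_trace
#' @param trace A trace tibble.
#' @export
write_trace <- function(trace, path) {
  validate_trace(trace)
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Run the full simulation-to-evaluation pipeline
#'
#' Simulates a labelled step dataset, detects stance phases, extracts the
#' ten predictors, splits record-wise into training and held-out sets, fits
#' the trainable models (stepwise regression; conditional-inference tree and
#' random forest, each for angle prediction and class classification),
#' applies the published fixed-coefficient regression, and evaluates every
#' model on the held-out set with error metrics, Bland-Altman agreement and
#' confusion-matrix statistics.
#'
#' One master `seed` drives every stage deterministically: stage seeds are
#' `seed + 1` (simulation), `seed + 2` (split) and `seed + 3` (model
#' fitting), each applied in an isolated RNG scope.
#'
#' @param n_ff,n_mf,n_rf Steps drawn per class distribution.
#' @param seed Master integer seed.
#' @param sim_config A [gait_sim_config()].
#' @param ev_config An [event_config()].
#' @param train_fraction Training fraction for [split_records()].
#' @param n_trees,mtry_grid,cv_folds Forest settings, see
#'   [fit_strike_forest()].
#' @param out_dir Optional directory to write run artifacts (manifest,
#'   feature table, predictions as CSV; evaluation reports as JSON). The
#'   directory must not already exist: an existing run is never silently
#'   overwritten.
#'
#' @return An object of class `"fsa_pipeline"`: list with `features`,
#'   `split`, `models`, `predictions` (held-out tibble with one prediction
#'   column per model), and `evaluation` (per-model angle metrics,
#'   Bland-Altman reports, confusion matrices and their metrics).
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(n_ff = 60, n_mf = 60, n_rf = 60, seed = 1,
#'                     n_trees = 50, mtry_grid = c(3, 5))
#' run$evaluation$class_metrics
#' }
run_pipeline <- function(n_ff, n_mf, n_rf, seed = 1,
                         sim_config = gait_sim_config(),
                         ev_config = event_config(),
                         train_fraction = 0.7,
                         n_trees = 500, mtry_grid = 2:5, cv_folds = 5,
                         out_dir = NULL) {
  if (!is.null(out_dir) && dir.exists(out_dir)) {
    stop("Output directory already exists: ", out_dir,
         " (refusing to overwrite a previous run).", call. = FALSE)
  }
  if (n_ff + n_mf + n_rf < 2) {
    stop("Need at least 2 simulated steps before any model can be trained.",
         call. = FALSE)
  }

  steps <- withr::with_seed(seed + 1,
                            simulate_steps(sim_config, n_ff, n_mf, n_rf))
  features <- compute_features(steps, ev_config)
  split <- split_records(features, train_fraction, seed = seed + 2)
  train <- split$train
  test <- split$test

  models <- withr::with_seed(seed + 3, list(
    published = published_mr_model(),
    stepwise = fit_stepwise_mr(train, "true_fsa_deg"),
    tree_pred = fit_strike_tree(train, "true_fsa_deg", "regression"),
    tree_class = fit_strike_tree(train, "true_class", "classification"),
    forest_pred = fit_strike_forest(train, "true_fsa_deg", "regression",
                                    n_trees = n_trees,
                                    mtry_grid = mtry_grid,
                                    cv_folds = cv_folds),
    forest_class = fit_strike_forest(train, "true_class", "classification",
                                     n_trees = n_trees,
                                     mtry_grid = mtry_grid,
                                     cv_folds = cv_folds)
  ))

  angle_models <- c("published", "stepwise", "tree_pred", "forest_pred")
  class_models <- c("published", "stepwise", "tree_class", "forest_class")

  predictions <- test
  for (m in angle_models) {
    predictions[[paste0("fsa_", m)]] <- predict(models[[m]], test)
  }
  for (m in class_models) {
    predictions[[paste0("fsp_", m)]] <- predict_fsp(models[[m]], test)
  }

  angle_metrics <- purrr::map_dfr(angle_models, function(m) {
    dplyr::bind_cols(
      tibble::tibble(model = m),
      prediction_metrics(test$true_fsa_deg, predictions[[paste0("fsa_", m)]])
    )
  })
  agreement <- purrr::map_dfr(angle_models, function(m) {
    dplyr::bind_cols(
      tibble::tibble(model = m),
      bland_altman(test$true_fsa_deg, predictions[[paste0("fsa_", m)]])
    )
  })
  confusions <- purrr::map(
    stats::setNames(class_models, class_models),
    function(m) confusion_fsp(test$true_class, predictions[[paste0("fsp_", m)]])
  )
  class_metrics <- purrr::map_dfr(class_models, function(m) {
    dplyr::bind_cols(tibble::tibble(model = m),
                     confusion_metrics(confusions[[m]]))
  })

  result <- structure(
    list(
      seed = seed,
      features = features,
      split = split,
      models = models,
      predictions = predictions,
      evaluation = list(
        angle_metrics = angle_metrics,
        agreement = agreement,
        confusions = confusions,
        class_metrics = class_metrics
      )
    ),
    class = "fsa_pipeline"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    utils::write.csv(dplyr::select(features, -dplyr::any_of("trace")),
                     file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(
        seed = seed,
        angle_metrics = angle_metrics,
        agreement = agreement,
        class_metrics = class_metrics,
        confusions = purrr::map(confusions, function(m) matrix(m, 3, 3))
      ),
      file.path(out_dir, "evaluation.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  result
}

#' @export
print.fsa_pipeline <- function(x, ...) {
  cat("Foot strike pipeline run (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  %d steps -> train %d / test %d\n",
              nrow(x$features), nrow(x$split$train), nrow(x$split$test)))
  cat("Held-out angle RMSE (deg):\n")
  am <- x$evaluation$angle_metrics
  for (i in seq_len(nrow(am))) {
    cat(sprintf("  %-12s %.2f\n", am$model[i], am$rmse[i]))
  }
  cm <- dplyr::filter(x$evaluation$class_metrics, .data$metric == "accuracy")
  cat("Held-out classification accuracy (%):\n")
  for (i in seq_len(nrow(cm))) {
    cat(sprintf("  %-12s %.1f\n", cm$model[i], round_half_up(cm$value_pct[i])))
  }
  invisible(x)
}
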