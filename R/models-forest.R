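#' Random forest for foot strike prediction or classification
#'
#' Bootstrap-aggregated trees via \pkg{randomForest}, with the per-split
#' candidate-feature count (`mtry`) tuned by k-fold cross-validation over a
#' small grid: the setting with the lowest CV root mean squared error
#' (regression) or the highest mean CV accuracy (classification) wins, with
#' ties going to the smaller `mtry`. The final forest is refit on all
#' training rows at the chosen `mtry`; out-of-bag error and impurity-decrease
#' variable importance (mean decrease in Gini for classification, node
#' purity for regression) are reported.
#'
#' @inheritParams fit_strike_tree
#' @param n_trees Number of trees. Default 500.
#' @param mtry_grid Candidate-feature counts to tune over. Default `2:5`.
#' @param cv_folds Number of cross-validation folds. Default 5.
#'
#' @return An object of class `"fsa_forest"`: list with the fitted
#'   `randomForest` (`fit`), chosen `mtry`, `cv_results` tibble, `oob_error`
#'   (RMSE in degrees for regression, error fraction for classification),
#'   and `importance` (named vector over the predictors). Supports
#'   [predict()] and [glance()][generics::glance].
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(x = runif(120), z = runif(120))
#' d$y <- 5 * d$x + rnorm(120)
#' f <- fit_strike_forest(d, "y", "regression", c("x", "z"),
#'                        n_trees = 50, mtry_grid = 1:2, cv_folds = 3)
#' f$mtry
fit_strike_forest <- function(data, response,
                              task = c("regression", "classification"),
                              predictors = NULL, n_trees = 500,
                              mtry_grid = 2:5, cv_folds = 5) {
  task <- match.arg(task)
  stopifnot(is.data.frame(data), nrow(data) > 0, response %in% names(data))
  if (is.null(predictors)) {
    predictors <- intersect(feature_names(), names(data))
  }
  stopifnot(all(predictors %in% names(data)), n_trees >= 1, cv_folds >= 2)
  mtry_grid <- mtry_grid[mtry_grid <= length(predictors)]
  stopifnot(length(mtry_grid) >= 1)

  x <- data[predictors]
  y <- data[[response]]
  if (task == "classification") {
    if (!is.factor(y)) y <- factor(y)
    y <- droplevels(y)
  } else {
    stopifnot(is.numeric(y))
  }

  n <- nrow(x)
  fold <- sample(rep_len(seq_len(cv_folds), n))
  cv <- purrr::map_dfr(mtry_grid, function(m) {
    scores <- vapply(seq_len(cv_folds), function(k) {
      hold <- fold == k
      fit <- randomForest::randomForest(
        x = x[!hold, , drop = FALSE], y = y[!hold],
        mtry = m, ntree = n_trees
      )
      pred <- stats::predict(fit, x[hold, , drop = FALSE])
      if (task == "regression") {
        sqrt(mean((pred - y[hold])^2))
      } else {
        mean(pred == y[hold])
      }
    }, numeric(1))
    tibble::tibble(
      mtry = m,
      metric = if (task == "regression") "rmse" else "accuracy",
      score = mean(scores)
    )
  })
  best <- if (task == "regression") {
    cv$mtry[which.min(cv$score)]
  } else {
    cv$mtry[which.max(cv$score)]
  }

  fit <- randomForest::randomForest(x = x, y = y, mtry = best,
                                    ntree = n_trees)
  imp <- randomForest::importance(fit)
  oob <- if (task == "regression") {
    sqrt(fit$mse[n_trees])
  } else {
    unname(fit$err.rate[n_trees, "OOB"])
  }

  structure(
    list(fit = fit, task = task, response = response,
         predictors = predictors, mtry = best, n_trees = n_trees,
         cv_results = cv, oob_error = oob,
         importance = stats::setNames(imp[, 1], rownames(imp))),
    class = "fsa_forest"
  )
}

#' @export
predict.fsa_forest <- function(object, newdata, ...) {
  missing <- setdiff(object$predictors, names(newdata))
  if (length(missing) > 0) {
    stop("Missing predictor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- stats::predict(object$fit, newdata[object$predictors])
  if (object$task == "regression") unname(out) else unname(out)
}

#' @export
print.fsa_forest <- function(x, ...) {
  cat(sprintf(
    "Random forest (%s): %d trees, mtry = %d, OOB %s = %.3f\n",
    x$task, x$n_trees, x$mtry,
    if (x$task == "regression") "RMSE (deg)" else "error rate",
    x$oob_error
  ))
  invisible(x)
}

#' Classify foot strike pattern with any fitted angle or class model
#'
#' Routes a model's predictions to a pattern class: models that predict a
#' continuous angle (published regression, stepwise regression, regression
#' tree/forest) are thresholded through [classify_fsp()] with the same
#' cut-offs used for truth labelling (no recalibration); classification
#' models return their class prediction directly.
#'
#' @param model A fitted `fsa_published_mr`, `fsa_stepwise`, `fsa_tree` or
#'   `fsa_forest` object.
#' @param newdata Data frame of predictor columns.
#' @param ff_upper,rf_lower Class cut-offs in degrees, see [classify_fsp()].
#'
#' @return Factor of classes with levels `RF`, `MF`, `FF`.
#' @export
predict_fsp <- function(model, newdata, ff_upper = -1.6, rf_lower = 8.0) {
  pred <- stats::predict(model, newdata)
  if (is.factor(pred)) {
    factor(as.character(pred), levels = fsp_levels())
  } else {
    classify_fsp(pred, ff_upper = ff_upper, rf_lower = rf_lower)
  }
}
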