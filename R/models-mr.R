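#' Record-wise train/test split
#'
#' Randomly partitions step records into a training and a held-out test set.
#' The training size is `round(train_fraction * n)`; shuffling uses R's RNG
#' stream (use [set.seed()] or the `seed` argument for reproducibility).
#'
#' @param records Data frame of step records (one row per step).
#' @param train_fraction Fraction of records assigned to training, in (0, 1).
#'   Default 0.7.
#' @param seed Optional integer; when supplied the split is drawn in an
#'   isolated RNG scope via [withr::with_seed()].
#'
#' @return List with elements `train` and `test` (disjoint, exhaustive).
#' @export
#' @examples
#' split <- split_records(data.frame(x = 1:10), train_fraction = 0.7, seed = 1)
#' nrow(split$train) # 7
split_records <- function(records, train_fraction = 0.7, seed = NULL) {
  stopifnot(is.data.frame(records),
            is.numeric(train_fraction), length(train_fraction) == 1,
            train_fraction > 0, train_fraction < 1)
  n <- nrow(records)
  if (n < 2) {
    stop("Need at least 2 records to split.", call. = FALSE)
  }
  draw <- function() sample.int(n)
  ord <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  n_train <- round(train_fraction * n)
  list(
    train = records[sort(ord[seq_len(n_train)]), , drop = FALSE],
    test = records[sort(ord[seq.int(n_train + 1, n)]), , drop = FALSE]
  )
}

#' Stepwise multiple linear regression by partial-F p-values
#'
#' Forward-entry / backward-removal stepwise selection in the SPSS style:
#' at each round the candidate with the smallest partial-F p-value enters if
#' that p-value is at most `p_enter`, then any retained predictor whose
#' partial-F p-value is at least `p_remove` is removed (largest first).
#' Iteration stops when no entry or removal changes the model. Candidates
#' that are perfectly collinear with the current model (singular partial fit)
#' are skipped with a warning.
#'
#' The reported AIC/BIC use the Gaussian linear-model forms with the additive
#' constant dropped: `AIC = n log(RSS/n) + 2(k+1)`,
#' `BIC = n log(RSS/n) + (k+1) log(n)` for `k` slopes.
#'
#' @param data Data frame containing response and candidate predictors.
#' @param response Name of the numeric response column (degrees).
#' @param predictors Character vector of candidate predictor columns.
#'   Defaults to [feature_names()] present in `data`.
#' @param p_enter Entry threshold on the partial-F p-value. Default 0.05.
#' @param p_remove Removal threshold, must exceed `p_enter`. Default 0.10.
#'
#' @return An object of class `"fsa_stepwise"`: a list with the final `lm`
#'   fit (`fit`), `selected` predictors in entry order, the selection `path`,
#'   and fit statistics (`r_squared`, `adj_r_squared`, `sigma`, `aic`, `bic`,
#'   `df_residual`, `n`). Supports [predict()], [tidy()][generics::tidy] and
#'   [glance()][generics::glance].
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
#' d$y <- 2 * d$a - d$b + rnorm(200)
#' fit_stepwise_mr(d, "y", c("a", "b", "c"))$selected
fit_stepwise_mr <- function(data, response, predictors = NULL,
                            p_enter = 0.05, p_remove = 0.10) {
  stopifnot(is.data.frame(data), response %in% names(data),
            p_enter < p_remove)
  if (is.null(predictors)) {
    predictors <- intersect(feature_names(), names(data))
  }
  stopifnot(length(predictors) >= 1, all(predictors %in% names(data)))
  if (nrow(data) <= length(predictors) + 2) {
    stop("Too few rows for stepwise selection over ", length(predictors),
         " candidates.", call. = FALSE)
  }

  selected <- character()
  path <- list()
  fit <- stats::lm(stats::reformulate("1", response), data = data)

  partial_p <- function(tab) {
    # add1/drop1 tables: rows after the first describe candidate terms
    p <- tab[["Pr(>F)"]]
    stats::setNames(p[-1], rownames(tab)[-1])
  }

  repeat {
    changed <- FALSE
    remaining <- setdiff(predictors, selected)
    if (length(remaining) > 0) {
      tab <- stats::add1(fit,
                         scope = stats::reformulate(c(selected, remaining)),
                         test = "F")
      p <- partial_p(tab)
      singular <- names(p)[is.na(p)]
      if (length(singular) > 0) {
        warning("Skipping collinear candidate(s): ",
                paste(singular, collapse = ", "), call. = FALSE)
        p <- p[!is.na(p)]
      }
      if (length(p) > 0 && min(p) <= p_enter) {
        entering <- names(p)[which.min(p)]
        selected <- c(selected, entering)
        fit <- stats::lm(stats::reformulate(selected, response), data = data)
        path[[length(path) + 1]] <- list(action = "enter", term = entering,
                                         p_value = min(p))
        changed <- TRUE
      }
    }
    if (length(selected) > 0) {
      tab <- stats::drop1(fit, test = "F")
      p <- partial_p(tab)
      if (length(p) > 0 && max(p, na.rm = TRUE) >= p_remove) {
        leaving <- names(p)[which.max(p)]
        selected <- setdiff(selected, leaving)
        fit <- stats::lm(
          stats::reformulate(if (length(selected) > 0) selected else "1",
                             response),
          data = data
        )
        path[[length(path) + 1]] <- list(action = "remove", term = leaving,
                                         p_value = max(p, na.rm = TRUE))
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  sm <- summary(fit)
  n <- length(stats::residuals(fit))
  rss <- sum(stats::residuals(fit)^2)
  k <- length(selected)
  structure(
    list(
      fit = fit,
      response = response,
      selected = selected,
      path = path,
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      sigma = sm$sigma,
      aic = n * log(rss / n) + 2 * (k + 1),
      bic = n * log(rss / n) + (k + 1) * log(n),
      df_residual = fit$df.residual,
      n = n
    ),
    class = "fsa_stepwise"
  )
}

#' @export
predict.fsa_stepwise <- function(object, newdata, ...) {
  unname(stats::predict(object$fit, newdata = newdata))
}

#' @export
print.fsa_stepwise <- function(x, ...) {
  cat("Stepwise FSA regression: ", length(x$selected), " predictor(s) [",
      paste(x$selected, collapse = ", "), "]\n", sep = "")
  cat(sprintf("R^2 = %.3f (adj %.3f), residual SE = %.2f deg, df = %d\n",
              x$r_squared, x$adj_r_squared, x$sigma, x$df_residual))
  invisible(x)
}
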