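#' Prediction-error metrics for foot strike angle
#'
#' Mean squared error, root mean squared error, mean absolute error and mean
#' absolute percentage error of predicted versus true angles. MAPE is a
#' unitless fraction, `mean(|true - pred| / |true|)`; records with a true
#' angle of exactly zero are excluded from MAPE only (their count is
#' reported), never from the other metrics.
#'
#' @param truth Numeric vector of true angles (degrees).
#' @param estimate Numeric vector of predicted angles, same length.
#'
#' @return One-row tibble: `mse`, `rmse`, `mae`, `mape`, `n`,
#'   `n_mape_excluded`.
#' @export
#' @examples
#' prediction_metrics(c(5, 10), c(6, 13)) # mse 5, rmse 2.24, mae 2, mape .25
prediction_metrics <- function(truth, estimate) {
  stopifnot(is.numeric(truth), is.numeric(estimate))
  if (length(truth) != length(estimate)) {
    stop("`truth` and `estimate` must have the same length.", call. = FALSE)
  }
  if (length(truth) == 0) {
    stop("Need at least one record.", call. = FALSE)
  }
  err <- truth - estimate
  nz <- truth != 0
  tibble::tibble(
    mse = mean(err^2),
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    mape = if (any(nz)) mean(abs(err[nz]) / abs(truth[nz])) else NA_real_,
    n = length(truth),
    n_mape_excluded = sum(!nz)
  )
}

#' Bland-Altman agreement between true and predicted angles
#'
#' Bias is the mean difference (true minus predicted); the 95% limits of
#' agreement are the bias plus/minus 1.96 sample standard deviations (n-1
#' denominator) of the differences; the maximum precision is the width
#' between the limits.
#'
#' @inheritParams prediction_metrics
#'
#' @return One-row tibble: `bias`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `max_precision`, `n`.
#' @export
#' @examples
#' bland_altman(c(1, 3), c(0, 0)) # bias 2, LoA [-0.77, 4.77]
bland_altman <- function(truth, estimate) {
  stopifnot(is.numeric(truth), is.numeric(estimate))
  if (length(truth) != length(estimate)) {
    stop("`truth` and `estimate` must have the same length.", call. = FALSE)
  }
  if (length(truth) < 2) {
    stop("Bland-Altman needs at least 2 paired records.", call. = FALSE)
  }
  d <- truth - estimate
  bias <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(
    bias = bias,
    sd_diff = s,
    loa_lower = bias - 1.96 * s,
    loa_upper = bias + 1.96 * s,
    max_precision = 2 * 1.96 * s,
    n = length(d)
  )
}

#' Three-class confusion matrix for foot strike pattern
#'
#' Cross-tabulates true against estimated classes with the fixed row/column
#' order RF, MF, FF (rows = true).
#'
#' @param truth,estimate Vectors (factor or character) of classes; every
#'   value must be one of `RF`, `MF`, `FF`.
#'
#' @return An integer matrix of class `"fsa_confusion"`.
#' @export
#' @examples
#' confusion_fsp(c("RF", "RF", "MF"), c("RF", "MF", "MF"))
confusion_fsp <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("`truth` and `estimate` must have the same length.", call. = FALSE)
  }
  lv <- fsp_levels()
  as_cls <- function(x, what) {
    x <- as.character(x)
    bad <- setdiff(unique(x), lv)
    if (length(bad) > 0) {
      stop("Unknown class label(s) in `", what, "`: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    factor(x, levels = lv)
  }
  tab <- table(true = as_cls(truth, "truth"),
               estimated = as_cls(estimate, "estimate"))
  structure(unclass(tab) + 0L, class = c("fsa_confusion", "matrix"),
            dimnames = list(true = lv, estimated = lv))
}

#' Accuracy, recall and precision from a confusion matrix
#'
#' Model accuracy is total correct over total sample, per-class recall is
#' true positives over the true-class total (row), per-class precision is
#' true positives over the estimated-class total (column), each times 100.
#' Precision is undefined (`NA`) for a class never estimated.
#'
#' @param cm A 3x3 matrix (rows = true class) such as [confusion_fsp()]
#'   output or an entry of [published_confusion_matrices()].
#'
#' @return Tibble with columns `metric` (`accuracy`, `recall`, `precision`),
#'   `class` (`ALL` or a class), and `value_pct`.
#' @export
#' @examples
#' confusion_metrics(published_confusion_matrices()$mr)
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(3, 3)) || any(cm < 0)) {
    stop("`cm` must be a 3x3 matrix of nonnegative counts.", call. = FALSE)
  }
  total <- sum(cm)
  if (total == 0) {
    stop("`cm` contains no observations.", call. = FALSE)
  }
  lv <- if (!is.null(rownames(cm))) rownames(cm) else fsp_levels()
  correct <- diag(cm)
  recall <- 100 * correct / rowSums(cm)
  col_tot <- colSums(cm)
  precision <- ifelse(col_tot > 0, 100 * correct / col_tot, NA_real_)
  dplyr::bind_rows(
    tibble::tibble(metric = "accuracy", class = "ALL",
                   value_pct = 100 * sum(correct) / total),
    tibble::tibble(metric = "recall", class = lv,
                   value_pct = unname(recall)),
    tibble::tibble(metric = "precision", class = lv,
                   value_pct = unname(precision))
  )
}

#' @export
print.fsa_confusion <- function(x, ...) {
  cat("Foot strike pattern confusion matrix (rows = true)\n")
  print(matrix(x, 3, 3, dimnames = dimnames(x)))
  acc <- confusion_metrics(x)$value_pct[1]
  cat(sprintf("accuracy: %.1f%%\n", round_half_up(acc, 1)))
  invisible(x)
}
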