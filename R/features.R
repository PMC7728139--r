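#' Names of the ten stance-phase insole predictors
#'
#' Column order used throughout the package: impulse ratios over the full
#' stance and the first third, peak-force ratios, peak loading-rate (RFD)
#' ratios, and the natural log of the stance-percent at which each sensor's
#' RFD peaks.
#'
#' @return Character vector of length 10.
#' @export
feature_names <- function() {
  c("ir_fore", "ir_aft", "ir_fore_0_33", "ir_aft_0_33",
    "pf_fore", "pf_aft", "rfd_fore", "rfd_aft",
    "ln_pct_rfd_fore", "ln_pct_rfd_aft")
}

#' Impulse of one sensor over a sample window
#'
#' Trapezoidal time integral of the chosen force channel between two sample
#' indices (inclusive).
#'
#' @param trace A trace tibble.
#' @param from,to 1-based sample indices delimiting the window, `from < to`.
#' @param sensor One of `"fore"`, `"aft"`, `"total"`.
#'
#' @return Impulse in Newton-seconds.
#' @export
#' @examples
#' tr <- tibble::tibble(
#'   time_s = seq(0, 0.2, by = 0.01),
#'   force_fore_N = 50, force_aft_N = 0, force_total_N = 50
#' )
#' impulse(tr, 1, nrow(tr), "fore") # 50 N * 0.2 s = 10 N s
impulse <- function(trace, from, to, sensor = c("total", "fore", "aft")) {
  validate_trace(trace)
  sensor <- match.arg(sensor)
  stopifnot(from >= 1, to <= nrow(trace))
  if (to <= from) {
    stop("Empty impulse window: `to` must exceed `from`.", call. = FALSE)
  }
  col <- switch(sensor,
                fore = "force_fore_N",
                aft = "force_aft_N",
                total = "force_total_N")
  idx <- from:to
  pracma::trapz(trace$time_s[idx], trace[[col]][idx])
}

#' Extract the ten stance-phase predictors from one trace
#'
#' Computes, over the detected stance window: the fore/aft impulse ratios to
#' the total-foot impulse (full stance and first third, where the first third
#' runs from IC to `IC + round((TO - IC)/3)` inclusive), the fore/aft peak
#' force ratios, the fore/aft peak loading-rate (RFD) ratios, and the natural
#' logarithm of the stance-phase percent (IC = 0%, TO = 100%) at which each
#' sensor's loading rate peaks. Loading rates are backward first differences;
#' the first frame wins RFD ties. Impulse and peak-force ratios lie in
#' \[0, 1\] and the two impulse-ratio pairs each sum to one; RFD ratios are
#' nonnegative but may exceed one, because each sensor's rate is maximized at
#' its own frame (a sensor can rise while the other falls).
#'
#' @param trace A trace tibble.
#' @param window A one-row tibble or list with `ic_index` and `to_index`, as
#'   returned by [segment_stance()].
#'
#' @return A one-row tibble with the [feature_names()] columns.
#' @export
#' @examples
#' set.seed(2)
#' tr <- synthesize_trace(25, gait_sim_config(noise_sd = 0))
#' extract_features(tr, segment_stance(tr))
extract_features <- function(trace, window) {
  validate_trace(trace)
  ic <- as.integer(window$ic_index)
  to <- as.integer(window$to_index)
  stopifnot(length(ic) == 1, length(to) == 1)
  if (!(ic >= 1 && ic < to && to <= nrow(trace))) {
    stop("Invalid stance window [", ic, ", ", to, "] for a trace of ",
         nrow(trace), " samples.", call. = FALSE)
  }

  imp_total <- impulse(trace, ic, to, "total")
  if (imp_total <= 0) {
    stop("Degenerate stance: total impulse over the window is not positive.",
         call. = FALSE)
  }
  ir_fore <- impulse(trace, ic, to, "fore") / imp_total
  ir_aft <- 1 - ir_fore

  third_end <- ic + round((to - ic) / 3)
  imp_total_33 <- impulse(trace, ic, third_end, "total")
  if (imp_total_33 <= 0) {
    stop("Degenerate stance: total impulse over the first third is not ",
         "positive.", call. = FALSE)
  }
  ir_fore_0_33 <- impulse(trace, ic, third_end, "fore") / imp_total_33
  ir_aft_0_33 <- 1 - ir_fore_0_33

  idx <- ic:to
  pf_denom <- max(trace$force_total_N[idx])
  pf_fore <- max(trace$force_fore_N[idx]) / pf_denom
  pf_aft <- max(trace$force_aft_N[idx]) / pf_denom

  fs <- trace_sampling_rate(trace)
  rate <- function(col) c(NA_real_, diff(trace[[col]])) * fs
  r_fore <- rate("force_fore_N")[idx]
  r_aft <- rate("force_aft_N")[idx]
  r_total <- rate("force_total_N")[idx]
  rfd_denom <- max(r_total, na.rm = TRUE)
  if (!is.finite(rfd_denom) || rfd_denom <= 0) {
    stop("Degenerate stance: total loading rate never positive in window.",
         call. = FALSE)
  }
  rfd_fore <- max(r_fore, na.rm = TRUE) / rfd_denom
  rfd_aft <- max(r_aft, na.rm = TRUE) / rfd_denom

  pct_of_stance <- function(r, sensor) {
    if (all(is.na(r) | r <= 0)) {
      # a sensor that never loads has no rate peak to locate
      warning("The ", sensor, " sensor loading rate is never positive in ",
              "the stance window; its peak-RFD timing is undefined (NA).",
              call. = FALSE)
      return(NA_real_)
    }
    k <- which.max(replace(r, is.na(r), -Inf)) # first frame wins ties
    pct <- 100 * (k - 1) / (to - ic)
    if (pct <= 0) {
      stop("Peak ", sensor, " RFD located exactly at initial contact ",
           "(stance percent 0); its natural logarithm is undefined.",
           call. = FALSE)
    }
    pct
  }
  pct_fore <- pct_of_stance(r_fore, "fore")
  pct_aft <- pct_of_stance(r_aft, "aft")

  tibble::tibble(
    ir_fore = ir_fore, ir_aft = ir_aft,
    ir_fore_0_33 = ir_fore_0_33, ir_aft_0_33 = ir_aft_0_33,
    pf_fore = pf_fore, pf_aft = pf_aft,
    rfd_fore = rfd_fore, rfd_aft = rfd_aft,
    ln_pct_rfd_fore = log(pct_fore), ln_pct_rfd_aft = log(pct_aft)
  )
}

#' Compute the feature table for a set of simulated or recorded steps
#'
#' Runs event detection and feature extraction over every trace in a steps
#' tibble (as returned by [simulate_steps()]). Steps whose stance cannot be
#' delimited or whose features are degenerate are dropped with a warning
#' naming the step ids.
#'
#' @param steps Tibble with a `trace` list-column plus any per-step metadata
#'   columns (carried through to the result).
#' @param config An [event_config()].
#'
#' @return A tibble with one row per surviving step: the metadata columns of
#'   `steps` (minus `trace`) followed by the ten [feature_names()] columns.
#' @export
#' @examples
#' set.seed(5)
#' steps <- simulate_steps(gait_sim_config(), 2, 2, 2)
#' compute_features(steps)
compute_features <- function(steps, config = event_config()) {
  stopifnot(is.data.frame(steps), "trace" %in% names(steps))
  rows <- purrr::map(steps$trace, function(tr) {
    tryCatch({
      win <- segment_stance(tr, config)
      extract_features(tr, win)
    }, error = function(e) e)
  })
  failed <- purrr::map_lgl(rows, inherits, "error")
  if (any(failed)) {
    ids <- if ("step_id" %in% names(steps)) steps$step_id[failed] else which(failed)
    warning(sum(failed), " step(s) dropped during feature extraction (ids: ",
            paste(utils::head(ids, 10), collapse = ", "), "). First error: ",
            conditionMessage(rows[[which(failed)[1]]]), call. = FALSE)
  }
  meta <- dplyr::select(steps, -"trace")[!failed, , drop = FALSE]
  dplyr::bind_cols(meta, dplyr::bind_rows(rows[!failed]))
}

#' Screen feature distributions for non-normality
#'
#' Computes standardized skewness and excess-kurtosis statistics (the moment
#' estimate divided by its standard error, SPSS definitions) for each
#' variable and flags those whose absolute statistic exceeds the critical
#' value, indicating a natural-log transform is warranted before parametric
#' modelling.
#'
#' @param features Data frame of numeric feature columns.
#' @param vars Character vector of columns to screen. Defaults to every
#'   numeric column.
#' @param critical Flagging threshold on the absolute standardized statistic.
#'   Default 2.58, the two-sided 1% normal critical value.
#'
#' @return A tibble with one row per variable: `variable`, `skewness_z`,
#'   `kurtosis_z`, `transform` (TRUE when either statistic exceeds
#'   `critical` in absolute value; `NA` for constant columns, whose moments
#'   are undefined).
#' @export
#' @examples
#' set.seed(1)
#' normality_screen(data.frame(g = rnorm(500), e = rexp(500)))
normality_screen <- function(features, vars = NULL, critical = 2.58) {
  stopifnot(is.data.frame(features))
  if (is.null(vars)) {
    vars <- names(features)[vapply(features, is.numeric, logical(1))]
  }
  n <- nrow(features)
  if (n < 8) {
    stop("Normality screening needs at least 8 rows.", call. = FALSE)
  }
  se_skew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  se_kurt <- 2 * se_skew * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
  purrr::map_dfr(vars, function(v) {
    x <- features[[v]]
    if (stats::sd(x) == 0) {
      return(tibble::tibble(variable = v, skewness_z = NA_real_,
                            kurtosis_z = NA_real_, transform = NA))
    }
    sz <- e1071::skewness(x, type = 2) / se_skew
    kz <- e1071::kurtosis(x, type = 2) / se_kurt
    tibble::tibble(variable = v, skewness_z = sz, kurtosis_z = kz,
                   transform = abs(sz) > critical | abs(kz) > critical)
  })
}
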