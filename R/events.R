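#' Event-detection configuration
#'
#' Thresholds for loading-rate based detection of initial contact (IC) and
#' toe off (TO) on the total (fore + aft) insole force.
#'
#' @param ic_threshold Loading rate in N/s above which the first frame marks
#'   initial contact. Default 1500.
#' @param to_threshold Loading rate in N/s below which the last frame marks
#'   toe off. Default -1500.
#'
#' @return An object of class `"event_config"`.
#' @export
#' @examples
#' event_config()
event_config <- function(ic_threshold = 1500, to_threshold = -1500) {
  stopifnot(is.numeric(ic_threshold), length(ic_threshold) == 1,
            is.numeric(to_threshold), length(to_threshold) == 1)
  if (!(ic_threshold > 0 && to_threshold < 0)) {
    stop("`ic_threshold` must be positive and `to_threshold` negative.",
         call. = FALSE)
  }
  structure(list(ic_threshold = ic_threshold, to_threshold = to_threshold),
            class = "event_config")
}

#' Per-sample loading rate of the total insole force
#'
#' Backward first difference of `force_total_N` scaled to N/s. The first
#' sample has no predecessor and is returned as `NA`.
#'
#' @param trace A trace tibble as produced by [synthesize_trace()] or
#'   [read_trace()].
#'
#' @return The input tibble with an added `loading_rate_N_s` column.
#' @export
#' @examples
#' tr <- tibble::tibble(
#'   time_s = (0:4) / 100,
#'   force_fore_N = c(0, 0, 20, 60, 120),
#'   force_aft_N = 0
#' )
#' tr$force_total_N <- tr$force_fore_N + tr$force_aft_N
#' loading_rate(tr)$loading_rate_N_s
loading_rate <- function(trace) {
  validate_trace(trace)
  fs <- trace_sampling_rate(trace)
  dplyr::mutate(
    trace,
    loading_rate_N_s = c(NA_real_, diff(.data$force_total_N)) * fs
  )
}

#' Delimit the stance phase from loading-rate threshold crossings
#'
#' Initial contact is the first frame whose total-force loading rate exceeds
#' `ic_threshold`; toe off is the last frame whose loading rate is below
#' `to_threshold`. Events are frame-resolution (no interpolation), matching
#' the 100 Hz frame-wise definition; the last-crossing rule at toe off guards
#' against mid-stance unloading dips.
#'
#' @param trace A trace tibble.
#' @param config An [event_config()].
#'
#' @return A one-row tibble with `ic_index`, `to_index` (1-based sample
#'   indices into `trace`), `ic_time_s`, `to_time_s` and `duration_s`.
#' @export
#' @examples
#' set.seed(1)
#' tr <- synthesize_trace(20, gait_sim_config(noise_sd = 0))
#' segment_stance(tr, event_config())
segment_stance <- function(trace, config = event_config()) {
  stopifnot(inherits(config, "event_config"))
  rate <- loading_rate(trace)$loading_rate_N_s
  ic_hits <- which(rate > config$ic_threshold)
  to_hits <- which(rate < config$to_threshold)
  if (length(ic_hits) == 0 || length(to_hits) == 0) {
    stop("no stance detected: ",
         if (length(ic_hits) == 0) "no loading-rate crossing above the IC threshold"
         else "no loading-rate crossing below the TO threshold",
         " (max rate ", round(max(rate, na.rm = TRUE)),
         " N/s, min rate ", round(min(rate, na.rm = TRUE)), " N/s).",
         call. = FALSE)
  }
  ic <- ic_hits[1]
  to <- to_hits[length(to_hits)]
  if (to <= ic) {
    stop("no stance detected: last toe-off crossing (sample ", to,
         ") does not follow the first initial-contact crossing (sample ",
         ic, ").", call. = FALSE)
  }
  tibble::tibble(
    ic_index = ic,
    to_index = to,
    ic_time_s = trace$time_s[ic],
    to_time_s = trace$time_s[to],
    duration_s = trace$time_s[to] - trace$time_s[ic]
  )
}
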