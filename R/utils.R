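# Internal validators shared across modules.

trace_columns <- function() {
  c("time_s", "force_fore_N", "force_aft_N", "force_total_N")
}

validate_trace <- function(trace, check_total = TRUE) {
  if (!is.data.frame(trace)) {
    stop("A trace must be a data frame.", call. = FALSE)
  }
  missing <- setdiff(trace_columns(), names(trace))
  if (length(missing) > 0) {
    stop("Trace is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trace) < 2) {
    stop("A trace needs at least 2 samples.", call. = FALSE)
  }
  dt <- diff(trace$time_s)
  if (any(dt <= 0)) {
    stop("Trace time stamps must be strictly increasing.", call. = FALSE)
  }
  if (max(dt) - min(dt) > 1e-6) {
    stop("Trace time stamps must be uniformly spaced (jitter above 1e-6 s).",
         call. = FALSE)
  }
  neg <- which(trace$force_fore_N < 0 | trace$force_aft_N < 0)
  if (length(neg) > 0) {
    stop("Negative force at row(s): ",
         paste(utils::head(neg, 5), collapse = ", "), call. = FALSE)
  }
  if (check_total) {
    resid <- abs(trace$force_total_N -
                   (trace$force_fore_N + trace$force_aft_N))
    tol <- 1e-9 * pmax(1, abs(trace$force_total_N))
    if (any(resid > tol)) {
      stop("`force_total_N` must equal fore + aft at every sample.",
           call. = FALSE)
    }
  }
  invisible(trace)
}

trace_sampling_rate <- function(trace) {
  1 / stats::median(diff(trace$time_s))
}

# Round half away from zero (report formatting; base round() is banker's).
round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
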