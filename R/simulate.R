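#' Simulator configuration for two-sensor insole force traces
#'
#' Bundles every tunable of the synthetic gait generator: sampling rate,
#' stance-duration and peak-force ranges, the class-conditional foot strike
#' angle (FSA) distributions, and the relative noise level.
#'
#' The class-conditional FSA distributions default to the fore-foot (FF),
#' mid-foot (MF) and rear-foot (RF) means and standard deviations observed in
#' treadmill-free overground running with a two-sensor pressure insole:
#' FF \eqn{-10.2 \pm 6.6}°, MF \eqn{3.0 \pm 2.8}°, RF \eqn{24.9 \pm 8.0}°.
#'
#' @param sampling_rate Sampling frequency in Hz. Default 100, the maximum
#'   rate of the two-sensor insole hardware the generator emulates.
#' @param stance_duration_range Length-2 numeric, stance duration bounds in
#'   seconds. Default `c(0.20, 0.35)`, typical of recreational running.
#' @param peak_force_range Length-2 numeric, peak total vertical force bounds
#'   in Newtons. Default `c(1500, 2500)` (roughly 2-3 body weights).
#' @param fsa_class_params Named list with elements `FF`, `MF`, `RF`, each a
#'   named numeric `c(mean = , sd = )` in degrees.
#' @param noise_sd Sensor noise as a fraction of peak force. Noise is
#'   heteroscedastic: per-sample standard deviation is
#'   `noise_sd * peak * sqrt(f / peak)`, so unloaded samples stay quiet (an
#'   unloaded capacitive insole does not chatter at tens of Newtons).
#' @param pad_s Seconds of near-zero force emitted before initial contact and
#'   after toe off so that loading-rate threshold crossings exist inside the
#'   buffer. Default 0.08 s.
#'
#' @return An object of class `"gait_sim_config"` (a validated list).
#' @seealso [sample_fsa()], [synthesize_trace()], [simulate_steps()]
#' @export
#' @examples
#' cfg <- gait_sim_config(noise_sd = 0)
#' cfg$fsa_class_params$RF
gait_sim_config <- function(sampling_rate = 100,
                            stance_duration_range = c(0.20, 0.35),
                            peak_force_range = c(1500, 2500),
                            fsa_class_params = list(
                              FF = c(mean = -10.2, sd = 6.6),
                              MF = c(mean = 3.0, sd = 2.8),
                              RF = c(mean = 24.9, sd = 8.0)
                            ),
                            noise_sd = 0.01,
                            pad_s = 0.08) {
  stopifnot(
    is.numeric(sampling_rate), length(sampling_rate) == 1, sampling_rate > 0,
    is.numeric(stance_duration_range), length(stance_duration_range) == 2,
    all(stance_duration_range > 0),
    stance_duration_range[1] <= stance_duration_range[2],
    is.numeric(peak_force_range), length(peak_force_range) == 2,
    all(peak_force_range > 0),
    peak_force_range[1] <= peak_force_range[2],
    is.numeric(noise_sd), length(noise_sd) == 1, noise_sd >= 0,
    is.numeric(pad_s), length(pad_s) == 1, pad_s >= 0
  )
  if (!all(c("FF", "MF", "RF") %in% names(fsa_class_params))) {
    stop("`fsa_class_params` must contain elements FF, MF and RF.", call. = FALSE)
  }
  for (cl in c("FF", "MF", "RF")) {
    p <- fsa_class_params[[cl]]
    if (!is.numeric(p) || !all(c("mean", "sd") %in% names(p)) || p[["sd"]] < 0) {
      stop("Each class entry needs numeric `mean` and nonnegative `sd`.",
           call. = FALSE)
    }
  }
  structure(
    list(
      sampling_rate = sampling_rate,
      stance_duration_range = stance_duration_range,
      peak_force_range = peak_force_range,
      fsa_class_params = fsa_class_params,
      noise_sd = noise_sd,
      pad_s = pad_s
    ),
    class = "gait_sim_config"
  )
}

#' Draw foot strike angles from a class-conditional distribution
#'
#' Samples FSA values (degrees) from the Gaussian attached to one foot strike
#' pattern class in a [gait_sim_config()].
#'
#' @param config A [gait_sim_config()].
#' @param class One of `"FF"`, `"MF"`, `"RF"`.
#' @param n Number of draws, a positive integer.
#'
#' @return Numeric vector of `n` angles in degrees.
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_fsa(gait_sim_config(), "RF", 1000))
sample_fsa <- function(config, class, n) {
  stopifnot(inherits(config, "gait_sim_config"),
            is.numeric(n), length(n) == 1, n >= 1)
  if (!is.character(class) || length(class) != 1 ||
      !class %in% names(config$fsa_class_params)) {
    stop("Unknown foot strike class: ", paste(class, collapse = ", "),
         ". Expected one of ", paste(names(config$fsa_class_params),
                                     collapse = ", "), ".", call. = FALSE)
  }
  p <- config$fsa_class_params[[class]]
  stats::rnorm(n, mean = p[["mean"]], sd = p[["sd"]])
}

# Raised-cosine pulse with independent rise and fall halves. Zero outside
# [onset, onset + rise + fall]; nonnegative, peak = amp. The default fall is
# the smooth cosine half; `fall_shape = "quarter"` ends with a quarter-cosine
# instead (maximum unloading rate at the end), modelling the abrupt force
# drop at toe off.
raised_cosine_pulse <- function(t, onset, rise, fall, amp,
                                fall_shape = c("cosine", "quarter")) {
  fall_shape <- match.arg(fall_shape)
  y <- numeric(length(t))
  up <- t >= onset & t < onset + rise
  dn <- t >= onset + rise & t <= onset + rise + fall
  y[up] <- amp * 0.5 * (1 - cos(pi * (t[up] - onset) / rise))
  tau <- t[dn] - onset - rise
  y[dn] <- if (fall_shape == "cosine") {
    amp * 0.5 * (1 + cos(pi * tau / fall))
  } else {
    amp * cos(pi * tau / (2 * fall))
  }
  y
}

# Maps FSA (degrees) to the waveform parameter set. `u` is a bounded
# rearfoot-ness score; every pulse parameter is linear in u so the extracted
# aft-side features are monotone in the generating angle. Times are fractions
# of stance duration, amplitudes are relative (the trace is renormalized to
# the requested peak force afterwards).
strike_pulse_params <- function(fsa) {
  # load sharing saturates for extreme rear-foot strikes: beyond a fully
  # heel-first contact the aft shares cannot keep growing
  u <- min(stats::plogis((fsa - 6) / 8), 0.97)
  active_onset <- 0.045 + 0.06 * u
  # rise is capped so the propulsive pulse always decays to zero by toe off
  active_rise <- min(0.24 + 0.65 * u, 0.905 - 0.06 * u)
  list(
    u = u,
    # aft sensor: a small heel-touch shoulder at contact plus the main
    # roll-on pulse whose rise (and hence rate peak) sits later in stance
    heel = list(onset = 0, rise = 0.22 - 0.10 * u, fall = 0.12,
                amp = 0.48 * (0.22 - 0.10 * u)),
    aft2 = list(onset = 0.05, rise = 0.33, fall = 0.20, amp = 0.60 * u),
    # fore sensor: early impact bump plus a broad propulsive pulse
    bump = list(onset = 0.05, rise = 0.16, fall = 0.12,
                amp = 0.505 - 0.455 * u),
    active = list(onset = active_onset, rise = active_rise,
                  fall = 1 - active_onset - active_rise,
                  amp = 0.70 - 0.285 * u)
  )
}

#' Synthesize one stance-phase force trace for a known foot strike angle
#'
#' Builds a two-sensor (fore/aft) vertical-force waveform over a single stance
#' phase. Each sensor is a sum of smooth raised-cosine pulses: the aft (heel)
#' sensor carries one impact/roll-off pulse, the fore sensor an early impact
#' bump plus a broad propulsive pulse. Pulse amplitudes and timings are driven
#' by a bounded logistic function of `fsa`, so that aft-side load shares
#' (impulse, peak force, peak loading rate, early-stance impulse) increase
#' monotonically with the generating angle, reproducing the fore/aft
#' load-sharing stratification of fore-, mid- and rear-foot strikes. The
#' buffer is padded with zero force on both sides so event detection has
#' threshold crossings to find.
#'
#' Stance duration and peak total force are drawn uniformly from the config
#' ranges (supply `duration`/`peak_force` to pin them). Draws come from R's
#' RNG stream, so results are reproducible under [set.seed()].
#'
#' @param fsa Foot strike angle in degrees (finite scalar).
#' @param config A [gait_sim_config()].
#' @param duration Optional stance duration in seconds, overriding the random
#'   draw.
#' @param peak_force Optional peak total force in Newtons, overriding the
#'   random draw.
#'
#' @return A trace tibble with columns `time_s`, `force_fore_N`,
#'   `force_aft_N`, `force_total_N`; `force_total_N` is exactly the sum of
#'   the two sensors at every sample.
#' @export
#' @examples
#' set.seed(7)
#' tr <- synthesize_trace(24, gait_sim_config(noise_sd = 0))
#' range(tr$force_total_N)
synthesize_trace <- function(fsa, config, duration = NULL, peak_force = NULL) {
  stopifnot(inherits(config, "gait_sim_config"),
            is.numeric(fsa), length(fsa) == 1, is.finite(fsa))
  fs <- config$sampling_rate
  if (is.null(duration)) {
    duration <- stats::runif(1, config$stance_duration_range[1],
                             config$stance_duration_range[2])
  }
  if (is.null(peak_force)) {
    peak_force <- stats::runif(1, config$peak_force_range[1],
                               config$peak_force_range[2])
  }
  stopifnot(duration > 0, peak_force > 0)

  n_pad <- ceiling(config$pad_s * fs)
  n_stance <- round(duration * fs)
  n <- n_stance + 2 * n_pad + 1
  time <- (seq_len(n) - 1) / fs
  # stance occupies [t0, t0 + duration]
  t0 <- n_pad / fs
  s <- (time - t0) / duration # stance-normalized time

  p <- strike_pulse_params(fsa)
  aft <- raised_cosine_pulse(s, p$heel$onset, p$heel$rise, p$heel$fall,
                             p$heel$amp) +
    raised_cosine_pulse(s, p$aft2$onset, p$aft2$rise, p$aft2$fall,
                        p$aft2$amp)
  fore <- raised_cosine_pulse(s, p$bump$onset, p$bump$rise, p$bump$fall,
                              p$bump$amp) +
    raised_cosine_pulse(s, p$active$onset, p$active$rise, p$active$fall,
                        p$active$amp, fall_shape = "quarter")
  scale <- peak_force / max(aft + fore)
  aft <- aft * scale
  fore <- fore * scale

  if (config$noise_sd > 0) {
    sd_aft <- config$noise_sd * peak_force * sqrt(pmax(aft, 0) / peak_force)
    sd_fore <- config$noise_sd * peak_force * sqrt(pmax(fore, 0) / peak_force)
    aft <- pmax(0, aft + stats::rnorm(n, 0, 1) * sd_aft)
    fore <- pmax(0, fore + stats::rnorm(n, 0, 1) * sd_fore)
  }

  tibble::tibble(
    time_s = time,
    force_fore_N = fore,
    force_aft_N = aft,
    force_total_N = fore + aft
  )
}

#' Classify a foot strike angle into fore-, mid- or rear-foot
#'
#' Applies the Altman-Davis angular cut-offs: fore foot (FF) for
#' `fsa < ff_upper`, mid foot (MF) for `ff_upper <= fsa <= rf_lower`
#' (both boundaries inclusive), rear foot (RF) for `fsa > rf_lower`.
#'
#' @param fsa Numeric vector of foot strike angles in degrees.
#' @param ff_upper Upper FF boundary in degrees (exclusive), default -1.6.
#' @param rf_lower Lower RF boundary in degrees (exclusive), default 8.0.
#'
#' @return Factor with levels `RF`, `MF`, `FF` (the conventional reporting
#'   order), same length as `fsa`.
#' @export
#' @examples
#' classify_fsp(c(-10.2, -1.6, 3, 8, 8.1, 24.9))
classify_fsp <- function(fsa, ff_upper = -1.6, rf_lower = 8.0) {
  stopifnot(is.numeric(fsa), is.numeric(ff_upper), is.numeric(rf_lower),
            ff_upper < rf_lower)
  if (any(!is.finite(fsa))) {
    stop("`fsa` must be finite.", call. = FALSE)
  }
  out <- ifelse(fsa < ff_upper, "FF", ifelse(fsa > rf_lower, "RF", "MF"))
  factor(out, levels = fsp_levels())
}

#' @rdname classify_fsp
#' @export
fsp_levels <- function() c("RF", "MF", "FF")

#' Simulate a labelled dataset of insole steps
#'
#' Draws per-class foot strike angles, synthesizes one stance-phase trace per
#' step, and returns a shuffled tibble of supervised records. The true class
#' label is derived from the drawn angle via [classify_fsp()], not from the
#' requested class (a nominally mid-foot draw landing beyond a cut-off is
#' labelled by its true angle, mirroring how measured steps are labelled by
#' their realized pattern regardless of the instructed condition).
#'
#' @param config A [gait_sim_config()].
#' @param n_ff,n_mf,n_rf Number of steps to draw from the FF, MF and RF
#'   angle distributions (nonnegative integers).
#'
#' @return A tibble with one row per step: `step_id`, `condition` (the
#'   requested class), `true_fsa_deg`, `true_class` (factor RF/MF/FF), and a
#'   `trace` list-column of trace tibbles.
#' @export
#' @examples
#' set.seed(42)
#' steps <- simulate_steps(gait_sim_config(), n_ff = 3, n_mf = 3, n_rf = 3)
#' dplyr::count(steps, true_class)
simulate_steps <- function(config, n_ff, n_mf, n_rf) {
  stopifnot(inherits(config, "gait_sim_config"),
            n_ff >= 0, n_mf >= 0, n_rf >= 0)
  counts <- c(FF = n_ff, MF = n_mf, RF = n_rf)
  condition <- rep(names(counts), counts)
  n <- length(condition)
  if (n == 0) {
    return(tibble::tibble(
      step_id = integer(), condition = character(),
      true_fsa_deg = numeric(),
      true_class = factor(character(), levels = fsp_levels()),
      trace = list()
    ))
  }
  fsa <- numeric(n)
  for (cl in names(counts)) {
    idx <- condition == cl
    if (any(idx)) fsa[idx] <- sample_fsa(config, cl, sum(idx))
  }
  traces <- lapply(fsa, synthesize_trace, config = config)
  ord <- sample.int(n)
  tibble::tibble(
    step_id = seq_len(n),
    condition = condition[ord],
    true_fsa_deg = fsa[ord],
    true_class = classify_fsp(fsa[ord]),
    trace = traces[ord]
  )
}
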