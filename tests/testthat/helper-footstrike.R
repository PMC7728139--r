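# Shared fixtures, all generated in code.

noiseless_config <- function(...) gait_sim_config(noise_sd = 0, ...)

# One noiseless trace with pinned stance duration and peak force.
pinned_trace <- function(fsa, duration = 0.28, peak = 2000,
                         config = noiseless_config()) {
  synthesize_trace(fsa, config, duration = duration, peak_force = peak)
}

features_of <- function(trace) {
  extract_features(trace, segment_stance(trace))
}

# Feature table drawn from the published regression's data-generating
# process: independent predictors, response = published model + Gaussian
# noise. Used for parameter-recovery oracles.
published_dgp <- function(n, sigma = 5.1) {
  m <- published_mr_model()
  x <- tibble::tibble(
    ir_aft = stats::runif(n),
    pf_fore = stats::runif(n),
    rfd_aft = stats::runif(n),
    ir_aft_0_33 = stats::runif(n),
    pf_aft = stats::runif(n),
    ln_pct_rfd_fore = stats::runif(n, 1, 4.5),
    ln_pct_rfd_aft = stats::runif(n, 1, 4.5)
  )
  x$true_fsa_deg <- predict(m, x) + stats::rnorm(n, sd = sigma)
  x
}

# Published class-mean feature vectors (fraction convention), one row per
# class, for evaluating the fixed-coefficient regression.
class_mean_features <- function() {
  published_class_profiles() |>
    dplyr::filter(.data$variable != "fsa") |>
    dplyr::select("variable", "class", "mean") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "mean")
}
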