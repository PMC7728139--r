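const_trace <- function(fore, aft, n = 21, fs = 100) {
  tibble::tibble(
    time_s = (seq_len(n) - 1) / fs,
    force_fore_N = rep_len(fore, n),
    force_aft_N = rep_len(aft, n),
    force_total_N = rep_len(fore + aft, n)
  )
}

test_that("impulse matches closed-form integrals", {
  # rectangle: 50 N over 0.2 s
  expect_equal(impulse(const_trace(50, 0), 1, 21, "fore"), 10)
  # triangle: 0 -> 100 N over 0.1 s
  tr <- const_trace(0, 0, n = 11)
  tr$force_fore_N <- seq(0, 100, by = 10)
  tr$force_total_N <- tr$force_fore_N
  expect_equal(impulse(tr, 1, 11, "fore"), 5)
  # raised cosine amp A width w integrates to A*w/2
  w <- 0.3
  t <- seq(0, w, by = 0.01)
  rc <- const_trace(0, 0, n = length(t))
  rc$force_fore_N <- 80 * 0.5 * (1 - cos(2 * pi * t / w))
  rc$force_total_N <- rc$force_fore_N
  expect_equal(impulse(rc, 1, nrow(rc), "fore"), 80 * w / 2,
               tolerance = 1e-3)

  expect_error(impulse(const_trace(1, 1), 5, 5), "Empty impulse window")
})

test_that("identical sensors give perfectly symmetric features", {
  tr <- pinned_trace(3)
  sym <- tr
  sym$force_fore_N <- tr$force_total_N / 2
  sym$force_aft_N <- tr$force_total_N / 2
  fv <- features_of(sym)
  expect_equal(fv$ir_fore, 0.5)
  expect_equal(fv$ir_aft, 0.5)
  expect_equal(fv$pf_fore, fv$pf_aft)
  expect_equal(fv$rfd_fore, fv$rfd_aft)
  expect_equal(fv$ln_pct_rfd_fore, fv$ln_pct_rfd_aft)
})

test_that("an absent aft sensor pushes every share to the fore sensor", {
  tr <- pinned_trace(-15)
  tr$force_aft_N <- 0
  tr$force_total_N <- tr$force_fore_N
  expect_warning(fv <- features_of(tr), "never positive")
  expect_equal(fv$ir_fore, 1)
  expect_equal(fv$ir_aft, 0)
  expect_equal(fv$pf_aft, 0)
  expect_true(is.na(fv$ln_pct_rfd_aft))
})

test_that("features are invariant to rescaling both sensors", {
  tr <- pinned_trace(18)
  window <- segment_stance(tr)
  base <- extract_features(tr, window)
  for (k in c(0.01, 3, 1000)) {
    sc <- tr
    sc$force_fore_N <- tr$force_fore_N * k
    sc$force_aft_N <- tr$force_aft_N * k
    sc$force_total_N <- tr$force_total_N * k
    expect_equal(extract_features(sc, window), base, tolerance = 1e-12)
  }
})

test_that("impulse-ratio pairs are complementary", {
  withr::with_seed(41, {
    for (fsa in runif(6, -20, 35)) {
      fv <- features_of(synthesize_trace(fsa, gait_sim_config()))
      expect_equal(fv$ir_fore + fv$ir_aft, 1, tolerance = 1e-9)
      expect_equal(fv$ir_fore_0_33 + fv$ir_aft_0_33, 1, tolerance = 1e-9)
    }
  })
})

test_that("a noiseless rear-foot trace sits inside the published RF envelope", {
  env <- published_class_profiles() |>
    dplyr::filter(.data$class == "RF", .data$variable != "fsa")
  for (dur in c(0.20, 0.25, 0.30, 0.35)) {
    fv <- features_of(pinned_trace(25, duration = dur))
    for (i in seq_len(nrow(env))) {
      x <- fv[[env$variable[i]]]
      expect_gte(x, env$mean[i] - 2 * env$sd[i])
      expect_lte(x, env$mean[i] + 2 * env$sd[i])
    }
  }
})

test_that("aft load shares rise monotonically with the generating angle", {
  sweep <- purrr::map_dfr(seq(-25, 40, by = 5), function(fsa) {
    features_of(pinned_trace(fsa))
  })
  for (v in c("ir_aft", "ir_aft_0_33", "pf_aft", "rfd_aft")) {
    expect_true(all(diff(sweep[[v]]) >= 0), label = paste(v, "nondecreasing"))
  }
  for (v in c("ir_fore", "ir_fore_0_33")) {
    expect_true(all(diff(sweep[[v]]) <= 0), label = paste(v, "nonincreasing"))
  }
})

test_that("class-mean angles reproduce the published feature ordering", {
  ff <- features_of(pinned_trace(-10.2))
  mf <- features_of(pinned_trace(3.0))
  rf <- features_of(pinned_trace(24.9))
  for (v in c("ir_aft", "ir_aft_0_33", "pf_aft", "rfd_aft")) {
    expect_lt(ff[[v]], mf[[v]])
    expect_lt(mf[[v]], rf[[v]])
  }
  for (v in c("ir_fore", "ir_fore_0_33", "pf_fore", "rfd_fore")) {
    expect_gt(ff[[v]], mf[[v]])
    expect_gt(mf[[v]], rf[[v]])
  }
})

test_that("normality screen flags skewed columns and not Gaussian ones", {
  withr::with_seed(51, {
    d <- data.frame(gaussian = rnorm(2000), skewed = rexp(2000))
    rep <- normality_screen(d)
    expect_false(rep$transform[rep$variable == "gaussian"])
    expect_true(rep$transform[rep$variable == "skewed"])
    expect_gt(abs(rep$skewness_z[rep$variable == "skewed"]), 2.58)
  })
  const <- normality_screen(data.frame(a = rnorm(100), b = rep(1, 100)))
  expect_true(is.na(const$transform[const$variable == "b"]))
  expect_error(normality_screen(data.frame(a = 1:5)), "at least 8 rows")
})

test_that("degenerate stances raise informative errors", {
  tr <- const_trace(0, 0)
  expect_error(extract_features(tr, list(ic_index = 1, to_index = 21)),
               "total impulse")
  tr2 <- pinned_trace(10)
  expect_error(extract_features(tr2, list(ic_index = 5, to_index = 4)),
               "Invalid stance window")
})
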