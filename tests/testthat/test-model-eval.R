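test_that("prediction metrics match hand arithmetic", {
  m <- prediction_metrics(c(5, 10), c(6, 13))
  expect_equal(m$mse, 5)
  expect_equal(m$rmse, sqrt(5))
  expect_equal(m$mae, 2)
  expect_equal(m$mape, 0.25)

  perfect <- prediction_metrics(c(-3, 7, 12), c(-3, 7, 12))
  expect_equal(unlist(perfect[c("mse", "rmse", "mae", "mape")]),
               c(mse = 0, rmse = 0, mae = 0, mape = 0))

  expect_error(prediction_metrics(1:3, 1:2), "same length")
})

test_that("rmse dominates mae and zero angles leave mape only", {
  withr::with_seed(81, {
    for (i in 1:10) {
      truth <- rnorm(50, sd = 10)
      pred <- truth + rnorm(50, sd = 4)
      m <- prediction_metrics(truth, pred)
      expect_gte(m$rmse, m$mae)
    }
  })
  m <- prediction_metrics(c(0, 10), c(1, 12))
  expect_identical(m$n_mape_excluded, 1L)
  expect_equal(m$mape, 0.2) # only the nonzero record
  expect_equal(m$mse, (1 + 4) / 2) # zero record kept everywhere else
})

test_that("Bland-Altman agreement matches its closed form", {
  ba <- bland_altman(c(1, 3), c(0, 0)) # differences 1, 3
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_lower, 2 - 1.96 * sqrt(2))
  expect_equal(ba$loa_upper, 2 + 1.96 * sqrt(2))
  expect_equal(ba$max_precision, 2 * 1.96 * sqrt(2))

  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$bias, 0)
  expect_equal(same$max_precision, 0)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("bias and spread recompose the mean squared error", {
  withr::with_seed(82, {
    truth <- rnorm(500, sd = 12)
    pred <- truth + rnorm(500, 1, 3)
    m <- prediction_metrics(truth, pred)
    ba <- bland_altman(truth, pred)
    n <- ba$n
    expect_equal(ba$bias^2 + ba$sd_diff^2 * (n - 1) / n, m$mse)
  })
})

test_that("confusion matrices have fixed ordering and validated labels", {
  cm <- confusion_fsp(c("RF", "RF", "MF"), c("RF", "MF", "MF"))
  expect_identical(dimnames(cm), list(true = c("RF", "MF", "FF"),
                                      estimated = c("RF", "MF", "FF")))
  expect_identical(sum(cm), 3L)
  expect_identical(cm["RF", "MF"], 1L)

  diag_cm <- confusion_fsp(rep(c("RF", "MF", "FF"), 4),
                           rep(c("RF", "MF", "FF"), 4))
  expect_identical(unname(diag(diag_cm)), rep(4L, 3))
  expect_identical(sum(diag_cm) - sum(diag(diag_cm)), 0L)

  one <- confusion_fsp("FF", "RF")
  expect_identical(sum(one), 1L)
  expect_identical(one["FF", "RF"], 1L)

  expect_error(confusion_fsp("RF", "XX"), "Unknown class label")
})

test_that("accuracy is the recall-weighted average over true classes", {
  withr::with_seed(83, {
    for (i in 1:20) {
      cm <- matrix(rpois(9, 20), 3,
                   dimnames = list(true = fsp_levels(),
                                   estimated = fsp_levels()))
      met <- confusion_metrics(cm)
      acc <- met$value_pct[met$metric == "accuracy"]
      rec <- met$value_pct[met$metric == "recall"]
      share <- rowSums(cm) / sum(cm)
      expect_equal(sum(share * rec), acc)
    }
  })
})

test_that("transposing a confusion matrix swaps recall and precision", {
  withr::with_seed(84, {
    cm <- matrix(rpois(9, 15) + 1, 3,
                 dimnames = list(true = fsp_levels(),
                                 estimated = fsp_levels()))
    a <- confusion_metrics(cm)
    b <- confusion_metrics(t(cm))
    expect_equal(a$value_pct[a$metric == "recall"],
                 b$value_pct[b$metric == "precision"])
    expect_equal(a$value_pct[a$metric == "precision"],
                 b$value_pct[b$metric == "recall"])
  })
})

test_that("degenerate matrices are handled explicitly", {
  met <- confusion_metrics(diag(c(5, 5, 5)))
  expect_true(all(met$value_pct == 100))

  never_ff <- matrix(c(5, 0, 0, 1, 4, 0, 2, 3, 0), 3, byrow = TRUE)
  m <- confusion_metrics(never_ff)
  expect_true(is.na(m$value_pct[m$metric == "precision"][3]))

  expect_error(confusion_metrics(matrix(0, 3, 3)), "no observations")
  expect_error(confusion_metrics(matrix(1, 2, 2)), "3x3")
})
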