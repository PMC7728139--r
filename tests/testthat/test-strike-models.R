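test_that("the published regression evaluates its affine form exactly", {
  zeros <- as.data.frame(as.list(stats::setNames(
    rep(0, 7), names(published_mr_model()$coefficients)
  )))
  expect_equal(eval_published_mr(zeros), -89.2)

  # affinity: prediction of a convex combination is the combination of
  # predictions
  withr::with_seed(61, {
    a <- published_dgp(5)
    b <- published_dgp(5)
    for (lam in c(0.2, 0.5, 0.9)) {
      mix <- a
      vars <- names(published_mr_model()$coefficients)
      mix[vars] <- lam * a[vars] + (1 - lam) * b[vars]
      expect_equal(eval_published_mr(mix),
                   lam * eval_published_mr(a) +
                     (1 - lam) * eval_published_mr(b))
    }
  })

  expect_error(eval_published_mr(data.frame(ir_aft = 0.3)),
               "Missing predictor")
})

test_that("class cut-offs are inclusive for mid foot and partition the line", {
  expect_identical(as.character(classify_fsp(-1.6)), "MF")
  expect_identical(as.character(classify_fsp(8.0)), "MF")
  expect_identical(as.character(classify_fsp(8.000001)), "RF")
  expect_identical(as.character(classify_fsp(-1.600001)), "FF")
  expect_identical(as.character(classify_fsp(24.9)), "RF")
  expect_identical(as.character(classify_fsp(-10.2)), "FF")

  withr::with_seed(62, {
    x <- runif(200, -50, 60)
    cls <- classify_fsp(x)
    expect_false(any(is.na(cls)))
    expect_identical(levels(cls), c("RF", "MF", "FF"))
  })
  expect_error(classify_fsp(NaN), "finite")
})

test_that("record-wise splits are disjoint, exhaustive and reproducible", {
  d <- data.frame(id = 1:10, x = rnorm(10))
  sp <- split_records(d, 0.7, seed = 1)
  expect_identical(nrow(sp$train), 7L)
  expect_identical(nrow(sp$test), 3L)
  expect_identical(sort(c(sp$train$id, sp$test$id)), 1:10)
  expect_identical(split_records(d, 0.7, seed = 1), sp)
  expect_error(split_records(d[1, , drop = FALSE]), "at least 2")
  expect_error(split_records(d, 1.2))
})

test_that("stepwise selection recovers a known sparse linear model", {
  withr::with_seed(63, {
    n <- 2000
    d <- as.data.frame(matrix(runif(n * 10), n,
                              dimnames = list(NULL, paste0("v", 1:10))))
    d$y <- 4 + 3 * d$v2 - 5 * d$v5 + 1.5 * d$v9 + rnorm(n, sd = 1)
    fit <- fit_stepwise_mr(d, "y", paste0("v", 1:10))
    expect_setequal(fit$selected, c("v2", "v5", "v9"))
    est <- coef(fit$fit)
    expect_equal(unname(est["v2"]), 3, tolerance = 0.05)
    expect_equal(unname(est["v5"]), -5, tolerance = 0.05)
    expect_equal(unname(est["v9"]), 1.5, tolerance = 0.05)
  })
})

test_that("null-response entries occur at the familywise min-p rate", {
  # with 10 independent null candidates and entry at p <= 0.05, the chance
  # of an empty final model is (1 - 0.05)^10 ~ 0.60; check the simulated
  # rate against that closed form within Monte-Carlo tolerance
  withr::with_seed(64, {
    empty <- vapply(1:30, function(i) {
      n <- 500
      d <- as.data.frame(matrix(rnorm(n * 10), n,
                                dimnames = list(NULL, paste0("v", 1:10))))
      d$y <- rnorm(n)
      length(fit_stepwise_mr(d, "y", paste0("v", 1:10))$selected) == 0
    }, logical(1))
    expect_lt(abs(mean(empty) - 0.95^10), 0.2)
  })
})

test_that("a noiseless linear response fits perfectly", {
  withr::with_seed(65, {
    d <- data.frame(a = runif(100), b = runif(100))
    d$y <- 2 + 7 * d$a - 3 * d$b
    # base lm warns about the (intentional) perfect fit
    fit <- suppressWarnings(fit_stepwise_mr(d, "y", c("a", "b")))
    expect_equal(fit$r_squared, 1)
    expect_lt(fit$sigma, 1e-8)
  })
})

test_that("perfectly collinear candidates are skipped with a warning", {
  withr::with_seed(66, {
    d <- data.frame(a = runif(300))
    d$b <- 1 - d$a
    d$y <- 10 * d$a + rnorm(300, sd = 0.5)
    expect_warning(fit <- fit_stepwise_mr(d, "y", c("a", "b")),
                   "collinear")
    expect_identical(fit$selected, "a")
  })
})

test_that("the inference tree finds a separable split and respects depth", {
  withr::with_seed(67, {
    d <- data.frame(x = c(runif(100, 0, 0.4), runif(100, 0.6, 1)),
                    z = runif(200))
    d$y <- ifelse(d$x < 0.5, -10, 10) + rnorm(200, sd = 0.5)
    fit <- fit_strike_tree(d, "y", "regression", c("x", "z"))
    expect_identical(fit$node$var, "x")
    expect_gt(fit$node$cut, 0.4)
    expect_lt(fit$node$cut, 0.6)
    expect_identical(tree_depth(fit), 1L)
  })
})

test_that("the significance gate keeps pure-noise roots as leaves", {
  withr::with_seed(68, {
    leafy <- vapply(1:20, function(i) {
      d <- as.data.frame(matrix(runif(200 * 10), 200,
                                dimnames = list(NULL, paste0("v", 1:10))))
      d$y <- rnorm(200)
      tree_depth(fit_strike_tree(d, "y", "regression",
                                 paste0("v", 1:10))) == 0
    }, logical(1))
    expect_gte(mean(leafy), 0.95)
  })
})

test_that("tree depth never exceeds the configured maximum", {
  withr::with_seed(69, {
    steps <- simulate_steps(gait_sim_config(), 120, 120, 120)
    feats <- compute_features(steps)
    for (md in c(2L, 4L)) {
      reg <- fit_strike_tree(feats, "true_fsa_deg", "regression",
                             max_depth = md)
      cls <- fit_strike_tree(feats, "true_class", "classification",
                             max_depth = md)
      expect_lte(tree_depth(reg), md)
      expect_lte(tree_depth(cls), md)
    }
  })
})

test_that("classification trees on balanced data split on an aft-side rate or load share first", {
  withr::with_seed(75, {
    steps <- simulate_steps(gait_sim_config(), 150, 150, 150)
    feats <- compute_features(steps)
    cls <- fit_strike_tree(feats, "true_class", "classification")
    expect_identical(cls$node$type, "split")
    # recorded for inspection; the exact winner depends on the draw
    message("first classification split variable: ", cls$node$var)
    expect_true(cls$node$var %in% c("rfd_aft", "ir_aft", "ir_aft_0_33",
                                    "pf_aft", "rfd_fore", "ir_fore",
                                    "ir_fore_0_33", "pf_fore"))
  })
})

test_that("small nodes become leaves", {
  withr::with_seed(70, {
    d <- data.frame(x = runif(15))
    d$y <- 20 * d$x
    fit <- fit_strike_tree(d, "y", "regression", "x", min_split = 20)
    expect_identical(tree_depth(fit), 0L)
  })
})

test_that("forests prefer informative features and average their trees", {
  withr::with_seed(71, {
    d <- data.frame(x = runif(200), z1 = runif(200), z2 = runif(200))
    d$y <- 10 * d$x + rnorm(200, sd = 0.3)
    f <- fit_strike_forest(d, "y", "regression", c("x", "z1", "z2"),
                           n_trees = 100, mtry_grid = 1:2, cv_folds = 3)
    expect_identical(names(which.max(f$importance)), "x")

    small <- fit_strike_forest(d, "y", "regression", c("x", "z1", "z2"),
                               n_trees = 3, mtry_grid = 2, cv_folds = 2)
    pred <- predict(small$fit, d[1:10, c("x", "z1", "z2")],
                    predict.all = TRUE)
    expect_equal(unname(pred$aggregate), unname(rowMeans(pred$individual)))
  })
})

test_that("out-of-bag error tracks held-out error", {
  withr::with_seed(72, {
    steps <- simulate_steps(gait_sim_config(), 250, 250, 250)
    feats <- compute_features(steps)
    sp <- split_records(feats, 0.7)
    f <- fit_strike_forest(sp$train, "true_class", "classification",
                           n_trees = 200, mtry_grid = 3, cv_folds = 3)
    holdout_acc <- mean(predict(f, sp$test) == sp$test$true_class)
    oob_acc <- 1 - f$oob_error
    expect_lte(abs(holdout_acc - oob_acc), 0.03)
  })
})

test_that("threshold classification routes angle models to classes", {
  rf_means <- class_mean_features() |> dplyr::filter(.data$class == "RF")
  fv <- rf_means
  fv$ir_aft <- 0.9
  expect_identical(as.character(predict_fsp(published_mr_model(), fv)), "RF")

  withr::with_seed(73, {
    d <- published_dgp(400, sigma = 2)
    d$true_class <- classify_fsp(d$true_fsa_deg)
    cls <- fit_strike_tree(d, "true_class", "classification",
                           names(published_mr_model()$coefficients))
    p <- predict_fsp(cls, d)
    expect_s3_class(p, "factor")
    expect_identical(levels(p), c("RF", "MF", "FF"))
  })
})

test_that("tidy and glance summarize fitted models", {
  withr::with_seed(74, {
    d <- published_dgp(500)
    fit <- fit_stepwise_mr(d, "true_fsa_deg")
    td <- tidy(fit)
    expect_true(all(c("term", "estimate", "p.value") %in% names(td)))
    gl <- glance(fit)
    expect_gte(gl$r.squared, gl$adj.r.squared)
    expect_identical(gl$df.residual, gl$nobs - gl$n.predictors - 1L)

    tr <- fit_strike_tree(d, "true_fsa_deg", "regression")
    nodes <- tidy(tr)
    expect_identical(sum(nodes$type == "leaf"),
                     sum(nodes$type == "split") + 1L)
    expect_identical(glance(tr)$depth, tree_depth(tr))
  })
})
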