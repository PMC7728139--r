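#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stepwise foot strike regression
#'
#' @param x An `"fsa_stepwise"` object.
#' @param ... Unused.
#' @return Tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.fsa_stepwise <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' @rdname tidy.fsa_stepwise
#' @export
glance.fsa_stepwise <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    adj.r.squared = x$adj_r_squared,
    sigma = x$sigma,
    AIC = x$aic,
    BIC = x$bic,
    df.residual = x$df_residual,
    nobs = x$n,
    n.predictors = length(x$selected)
  )
}

#' Tidy a conditional-inference tree
#'
#' @param x An `"fsa_tree"` object.
#' @param ... Unused.
#' @return Tibble with one row per node: `node`, `depth`, `type`, `variable`,
#'   `cut`, `p_adj`, `n`, `prediction`.
#' @export
tidy.fsa_tree <- function(x, ...) {
  rows <- list()
  walk <- function(nd, id, depth) {
    if (nd$type == "leaf") {
      pred <- if (is.numeric(nd$value)) format(round(nd$value, 2)) else
        nd$value
      rows[[length(rows) + 1]] <<- tibble::tibble(
        node = id, depth = depth, type = "leaf",
        variable = NA_character_, cut = NA_real_, p_adj = NA_real_,
        n = nd$n, prediction = pred
      )
    } else {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        node = id, depth = depth, type = "split",
        variable = nd$var, cut = nd$cut, p_adj = nd$p_adj,
        n = nd$n, prediction = NA_character_
      )
      walk(nd$left, 2L * id, depth + 1L)
      walk(nd$right, 2L * id + 1L, depth + 1L)
    }
  }
  walk(x$node, 1L, 0L)
  dplyr::bind_rows(rows)
}

#' @rdname tidy.fsa_tree
#' @export
glance.fsa_tree <- function(x, ...) {
  nodes <- tidy(x)
  tibble::tibble(
    depth = tree_depth(x),
    n.splits = sum(nodes$type == "split"),
    n.leaves = sum(nodes$type == "leaf"),
    nobs = x$n,
    alpha = x$alpha,
    max.depth = x$max_depth
  )
}

#' Tidy a random forest fit
#'
#' @param x An `"fsa_forest"` object.
#' @param ... Unused.
#' @return `tidy()`: per-variable impurity-decrease importance;
#'   `glance()`: one-row model summary.
#' @export
tidy.fsa_forest <- function(x, ...) {
  tibble::tibble(
    variable = names(x$importance),
    importance = unname(x$importance)
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname tidy.fsa_forest
#' @export
glance.fsa_forest <- function(x, ...) {
  tibble::tibble(
    n.trees = x$n_trees,
    mtry = x$mtry,
    oob.error = x$oob_error,
    nobs = length(x$fit$y)
  )
}

#' Tidy a confusion matrix into long counts
#'
#' @param x An `"fsa_confusion"` matrix.
#' @param ... Unused.
#' @return Tibble with columns `true`, `estimated`, `n`.
#' @export
tidy.fsa_confusion <- function(x, ...) {
  lv <- fsp_levels()
  tidyr::expand_grid(true = lv, estimated = lv) |>
    dplyr::mutate(n = purrr::map2_int(.data$true, .data$estimated,
                                      function(i, j) x[i, j]))
}
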