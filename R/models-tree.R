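#' Conditional-inference tree for foot strike prediction or classification
#'
#' Recursive partitioning with unbiased, significance-gated variable
#' selection in the conditional-inference framework: at every node each
#' candidate predictor is tested for association with the response using the
#' asymptotic permutation distribution of its linear statistic, p-values are
#' Bonferroni-adjusted across the candidates, and the node splits on the most
#' significant predictor only when its adjusted p-value is at most `alpha`.
#' The cut-point maximizes the standardized two-sample statistic (mean
#' difference for a numeric response, Pearson chi-square for a class
#' response) over admissible cuts. Nodes stop splitting at `max_depth`, below
#' `min_split` cases, or when no test passes the significance gate.
#'
#' Association tests: for a numeric response,
#' \eqn{z = \sqrt{n-1}\,|r|}{z = sqrt(n-1) |r|} with two-sided normal
#' p-value (r = Pearson correlation); for a class response,
#' \eqn{(n-1)\eta^2 \sim \chi^2_{K-1}}{(n-1) eta^2 ~ chisq(K-1)} where
#' \eqn{\eta^2} is the between-class share of the predictor's variance.
#' These are the closed-form permutation moments of the linear statistic, not
#' resampling approximations.
#'
#' @param data Training data frame.
#' @param response Response column name: numeric (degrees) for
#'   `task = "regression"`, factor for `task = "classification"`.
#' @param task `"regression"` (predict the angle) or `"classification"`
#'   (predict the pattern class).
#' @param predictors Candidate predictor columns; defaults to
#'   [feature_names()] present in `data`.
#' @param alpha Significance level of the splitting gate (adjusted p-value).
#'   Default 0.01.
#' @param max_depth Maximum depth of split nodes (root split = depth 1).
#'   Defaults to 8 for regression and 6 for classification.
#' @param min_split Minimum node size eligible for splitting. Default 20.
#' @param min_bucket Minimum child size. Default 7.
#'
#' @return An object of class `"fsa_tree"` supporting [predict()],
#'   [tidy()][generics::tidy] and `tree_depth()`.
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(x = runif(200), z = runif(200))
#' d$y <- ifelse(d$x > 0.5, 10, -10) + rnorm(200)
#' fit <- fit_strike_tree(d, "y", "regression", c("x", "z"))
#' tree_depth(fit)
fit_strike_tree <- function(data, response,
                            task = c("regression", "classification"),
                            predictors = NULL, alpha = 0.01,
                            max_depth = NULL, min_split = 20,
                            min_bucket = 7) {
  task <- match.arg(task)
  stopifnot(is.data.frame(data), nrow(data) > 0, response %in% names(data))
  if (is.null(predictors)) {
    predictors <- intersect(feature_names(), names(data))
  }
  stopifnot(length(predictors) >= 1, all(predictors %in% names(data)))
  if (is.null(max_depth)) {
    max_depth <- if (task == "regression") 8L else 6L
  }
  y <- data[[response]]
  if (task == "classification") {
    if (!is.factor(y)) y <- factor(y)
    levels_all <- levels(y)
  } else {
    stopifnot(is.numeric(y))
    levels_all <- NULL
  }
  x_mat <- as.matrix(data[predictors])

  node <- grow_ctree_node(x_mat, y, task, alpha, max_depth, min_split,
                          min_bucket, depth = 0L)
  structure(
    list(node = node, task = task, response = response,
         predictors = predictors, alpha = alpha, max_depth = max_depth,
         min_split = min_split, min_bucket = min_bucket,
         levels = levels_all, n = nrow(data)),
    class = "fsa_tree"
  )
}

# Association p-value of one predictor with the response (closed-form
# permutation moments, asymptotic reference distribution).
ctree_assoc_p <- function(x, y, task) {
  n <- length(x)
  if (stats::sd(x) == 0) return(1)
  if (task == "regression") {
    if (stats::sd(y) == 0) return(1)
    z <- sqrt(n - 1) * abs(stats::cor(x, y))
    2 * stats::pnorm(-z)
  } else {
    yy <- droplevels(y)
    k <- nlevels(yy)
    if (k < 2) return(1)
    m <- tapply(x, yy, mean)
    nk <- tabulate(yy)
    ssb <- sum(nk * (m - mean(x))^2)
    sst <- sum((x - mean(x))^2)
    stat <- (n - 1) * ssb / sst
    stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
}

# Best cut on one predictor: maximize the standardized two-sample statistic.
ctree_best_cut <- function(x, y, task, min_bucket) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  # admissible cut positions: between distinct values, both children large
  # enough
  pos <- which(diff(xs) > 0)
  pos <- pos[pos >= min_bucket & (n - pos) >= min_bucket]
  if (length(pos) == 0) return(NULL)
  best <- NULL
  if (task == "regression") {
    ys <- y[ord]
    cs <- cumsum(ys)
    tot <- cs[n]
    sdy <- stats::sd(ys)
    if (sdy == 0) return(NULL)
    nl <- pos
    stat <- abs(cs[pos] / nl - (tot - cs[pos]) / (n - nl)) /
      (sdy * sqrt(1 / nl + 1 / (n - nl)))
  } else {
    ys <- droplevels(y[ord])
    k <- nlevels(ys)
    ind <- stats::model.matrix(~ ys - 1)
    cs <- apply(ind, 2, cumsum)
    tot <- cs[n, ]
    stat <- vapply(pos, function(i) {
      o <- rbind(cs[i, ], tot - cs[i, ])
      e <- outer(c(i, n - i), tot) / n
      keep <- e > 0
      sum((o[keep] - e[keep])^2 / e[keep])
    }, numeric(1))
  }
  i <- pos[which.max(stat)]
  list(cut = (xs[i] + xs[i + 1]) / 2, stat = max(stat))
}

grow_ctree_node <- function(x_mat, y, task, alpha, max_depth, min_split,
                            min_bucket, depth) {
  n <- length(y)
  make_leaf <- function() {
    if (task == "regression") {
      list(type = "leaf", n = n, value = mean(y))
    } else {
      prob <- prop.table(table(y))
      list(type = "leaf", n = n, prob = as.numeric(prob),
           value = names(prob)[which.max(prob)])
    }
  }
  pure <- if (task == "regression") stats::sd(y) == 0 else
    length(unique(as.character(y))) < 2
  if (n < min_split || depth >= max_depth || pure) return(make_leaf())

  m <- ncol(x_mat)
  p <- vapply(seq_len(m), function(j) ctree_assoc_p(x_mat[, j], y, task),
              numeric(1))
  p_adj <- pmin(1, p * m) # Bonferroni across candidates
  j <- which.min(p_adj)
  if (p_adj[j] > alpha) return(make_leaf())

  cut <- ctree_best_cut(x_mat[, j], y, task, min_bucket)
  if (is.null(cut)) return(make_leaf())
  left <- x_mat[, j] <= cut$cut

  list(
    type = "split", n = n,
    var = colnames(x_mat)[j], cut = cut$cut, p_adj = p_adj[j],
    left = grow_ctree_node(x_mat[left, , drop = FALSE], y[left], task,
                           alpha, max_depth, min_split, min_bucket,
                           depth + 1L),
    right = grow_ctree_node(x_mat[!left, , drop = FALSE], y[!left], task,
                            alpha, max_depth, min_split, min_bucket,
                            depth + 1L)
  )
}

#' @rdname fit_strike_tree
#' @param tree An `"fsa_tree"`.
#' @export
tree_depth <- function(tree) {
  stopifnot(inherits(tree, "fsa_tree"))
  walk <- function(node) {
    if (node$type == "leaf") return(0L)
    1L + max(walk(node$left), walk(node$right))
  }
  walk(tree$node)
}

#' @export
predict.fsa_tree <- function(object, newdata, ...) {
  missing <- setdiff(object$predictors, names(newdata))
  if (length(missing) > 0) {
    stop("Missing predictor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  route <- function(node, row) {
    while (node$type == "split") {
      node <- if (row[[node$var]] <= node$cut) node$left else node$right
    }
    node$value
  }
  x <- newdata[object$predictors]
  out <- vapply(seq_len(nrow(x)), function(i) route(object$node, x[i, ]),
                if (object$task == "regression") numeric(1) else character(1))
  if (object$task == "classification") {
    factor(out, levels = object$levels)
  } else {
    out
  }
}

#' @export
print.fsa_tree <- function(x, ...) {
  cat(sprintf("Conditional-inference %s tree: depth %d, %d case(s)\n",
              x$task, tree_depth(x), x$n))
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(pad, "leaf n=", node$n, " -> ",
          if (is.numeric(node$value)) sprintf("%.2f", node$value)
          else node$value, "\n", sep = "")
    } else {
      cat(pad, node$var, " <= ", sprintf("%.4g", node$cut),
          " (p_adj=", sprintf("%.2g", node$p_adj), ", n=", node$n, ")\n",
          sep = "")
      show(node$left, indent + 1)
      show(node$right, indent + 1)
    }
  }
  show(x$node, 0)
  invisible(x)
}
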