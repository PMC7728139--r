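#' Published fixed-coefficient regression for foot strike angle
#'
#' The multiple-regression model reported for predicting foot strike angle
#' (degrees) from seven insole predictors:
#' \deqn{FSA = -89.2 + 94.4\,IR_{aft} + 62.3\,PF_{fore} + 17.9\,RFD_{aft}
#'   + 8.8\,IR_{aft,0-33} - 8.4\,PF_{aft} + 3.4\,\ln(\%RFD_{fore})
#'   + 1.8\,\ln(\%RFD_{aft})}
#' Ratio predictors are fractions in \[0, 1\]; the two timing predictors are
#' natural logs of a stance-phase percent (0-100 scale).
#'
#' @return An object of class `"fsa_published_mr"` usable with [predict()]
#'   and [eval_published_mr()].
#' @seealso [eval_published_mr()], [published_class_profiles()]
#' @export
#' @examples
#' m <- published_mr_model()
#' coef(m)
published_mr_model <- function() {
  structure(
    list(
      intercept = -89.2,
      coefficients = c(
        ir_aft = 94.4,
        pf_fore = 62.3,
        rfd_aft = 17.9,
        ir_aft_0_33 = 8.8,
        pf_aft = -8.4,
        ln_pct_rfd_fore = 3.4,
        ln_pct_rfd_aft = 1.8
      )
    ),
    class = "fsa_published_mr"
  )
}

#' @export
coef.fsa_published_mr <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.fsa_published_mr <- function(x, ...) {
  cat("Published foot strike angle regression (degrees)\n")
  print(round(coef(x), 1))
  invisible(x)
}

#' Predict foot strike angle with the published regression
#'
#' @param object A [published_mr_model()].
#' @param newdata Data frame containing the seven predictor columns (fraction
#'   convention for the ratio features).
#' @param ... Unused.
#'
#' @return Numeric vector of predicted angles in degrees.
#' @export
predict.fsa_published_mr <- function(object, newdata, ...) {
  vars <- names(object$coefficients)
  missing <- setdiff(vars, names(newdata))
  if (length(missing) > 0) {
    stop("Missing predictor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(newdata[vars])
  if (any(!is.finite(x))) {
    stop("Predictors must be finite.", call. = FALSE)
  }
  drop(object$intercept + x %*% object$coefficients)
}

#' @rdname predict.fsa_published_mr
#' @param features Data frame of extracted features.
#' @export
eval_published_mr <- function(features) {
  predict(published_mr_model(), features)
}

#' Published class-conditional feature profiles
#'
#' Mean and standard deviation of the foot strike angle and the ten insole
#' predictors for each foot strike pattern class, as reported for 3,489
#' overground running steps. Ratio variables are stored as fractions (the
#' source table prints percent); the log-timing variables are unitless.
#' These are published summary values shipped as data, not quantities this
#' package computes.
#'
#' @return A tibble with columns `variable`, `class`, `mean`, `sd`.
#' @seealso [published_mr_model()], [published_confusion_matrices()]
#' @export
#' @examples
#' dplyr::filter(published_class_profiles(), variable == "fsa")
published_class_profiles <- function() {
  profile <- function(class, fsa, vals) {
    tibble::tibble(
      variable = c("fsa", feature_names()),
      class = class,
      mean = c(fsa[1], vals$mean),
      sd = c(fsa[2], vals$sd)
    )
  }
  ff <- list(
    mean = c(.962, .038, .925, .075, .958, .081, .883, .145, 2.69, 2.72),
    sd = c(.057, .057, .098, .099, .082, .123, .128, .165, .55, .41)
  )
  mf <- list(
    mean = c(.893, .106, .772, .228, .933, .222, .700, .405, 2.27, 2.89),
    sd = c(.070, .070, .129, .129, .061, .134, .208, .220, .33, .35)
  )
  rf <- list(
    mean = c(.654, .346, .317, .682, .770, .599, .492, .912, 2.43, 3.25),
    sd = c(.115, .115, .163, .163, .115, .153, .162, .110, .23, .26)
  )
  dplyr::bind_rows(
    profile("FF", c(-10.2, 6.6), ff),
    profile("MF", c(3.0, 2.8), mf),
    profile("RF", c(24.9, 8.0), rf)
  )
}

#' Published validation-set confusion matrices
#'
#' The three 3x3 confusion matrices reported for foot strike pattern
#' classification of the 1,047 held-out steps by the fixed-coefficient
#' regression (`mr`), the conditional-inference tree (`tree`) and the random
#' forest (`forest`). Rows are the true class, columns the estimated class,
#' both ordered RF, MF, FF. Published counts shipped as data.
#'
#' @return Named list of three integer matrices.
#' @seealso [confusion_metrics()]
#' @export
#' @examples
#' sum(published_confusion_matrices()$mr) # 1047 validation steps
published_confusion_matrices <- function() {
  lv <- fsp_levels()
  mk <- function(v) {
    matrix(as.integer(v), nrow = 3, byrow = TRUE,
           dimnames = list(true = lv, estimated = lv))
  }
  list(
    mr = mk(c(621, 13, 0,
              26, 46, 48,
              5, 8, 280)),
    tree = mk(c(613, 21, 0,
                14, 88, 18,
                5, 6, 282)),
    forest = mk(c(611, 23, 0,
                  16, 92, 12,
                  3, 8, 282))
  )
}
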