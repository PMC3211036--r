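#' Simple linear calibration of a descriptor against experimental log P
#'
#' Ordinary least-squares fit of `y = a + b x` (through [stats::lm()])
#' with the diagnostic suite used throughout the package: Pearson `r`,
#' `r2`, the residual standard deviation `s = sqrt(SS_res / (n - 2))`,
#' and the F statistic `(n - 2) r2 / (1 - r2)`. Leave-one-out statistics
#' are added on request.
#'
#' @param x numeric predictor (descriptor values or a calculated log P
#'   column).
#' @param y numeric response (experimental log P).
#' @param x_kind optional label recording what the predictor was
#'   (`"raw_iset"` or `"calculated_logp"`).
#' @param class_label optional compound-class label.
#' @param loo if `TRUE`, also compute `press` and `q2_cv` via [loo_q2()].
#' @return object of class `iset_calibration`: list with `a` (intercept),
#'   `b` (slope), `n`, `r`, `r2`, `s`, `f`, and optionally `press`,
#'   `q2_cv`, plus the labels.
#' @examples
#' fit_ols(1:5, 2 * (1:5) + 1)
#' @export
fit_ols <- function(x, y, x_kind = NULL, class_label = NULL, loo = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("degenerate fit: predictor is constant")
  fit <- stats::lm(y ~ x)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  r <- stats::cor(x, y)
  r2 <- r^2
  s <- sqrt(sum(stats::resid(fit)^2) / (n - 2))
  f <- if (r2 >= 1) Inf else f_statistic(r2, n)   # exact fit: F is infinite
  out <- structure(
    list(a = a, b = b, n = n, r = r, r2 = r2, s = s,
         f = f, x_kind = x_kind, class_label = class_label),
    class = "iset_calibration"
  )
  if (loo) {
    cv <- loo_q2(x, y)
    out$press <- cv$press
    out$q2_cv <- cv$q2_cv
  }
  out
}

#' @export
print.iset_calibration <- function(x, digits = 4, ...) {
  cat("linear calibration",
      if (!is.null(x$class_label)) paste0(" [", x$class_label, "]"),
      if (!is.null(x$x_kind)) paste0(" (x: ", x$x_kind, ")"), "\n", sep = "")
  cat(sprintf("  y = %.*f + %.*f x   (n = %d)\n", digits, x$a, digits, x$b, x$n))
  cat(sprintf("  r = %.*f  r2 = %.*f  s = %.*f  F = %.1f\n",
              digits, x$r, digits, x$r2, digits, x$s, x$f))
  if (!is.null(x$q2_cv)) {
    cat(sprintf("  PRESS = %.*f  q2_cv = %.*f\n",
                digits, x$press, digits, x$q2_cv))
  }
  invisible(x)
}

#' F statistic of a simple linear regression
#'
#' `(n - 2) * r2 / (1 - r2)`, the null-hypothesis test of the slope.
#' Computed from the unrounded `r2`; published F values are extremely
#' sensitive to rounding of `r2` and should not be compared tightly.
#'
#' @param r2 coefficient of determination in `[0, 1)`.
#' @param n number of observations (>= 3).
#' @return the F statistic; `Inf` (with a warning) when `r2 == 1`.
#' @export
f_statistic <- function(r2, n) {
  if (!is.numeric(r2) || r2 < 0 || r2 > 1) stop("r2 must lie in [0, 1]")
  if (n < 3) stop("n must be >= 3")
  if (r2 == 1) {
    warning("r2 == 1: F statistic is infinite")
    return(Inf)
  }
  (n - 2) * r2 / (1 - r2)
}

#' Leave-one-out cross-validation of a simple linear regression
#'
#' Performs `n` explicit single-holdout refits, accumulating the
#' predictive residual sum of squares
#' `PRESS = sum (y_i - yhat_(-i))^2`, and returns
#' `q2_cv = 1 - PRESS / sum((y - mean(y))^2)` with the total sum of
#' squares taken about the full-sample mean. [press_shortcut()] computes
#' the same PRESS through the hat matrix and serves as an independent
#' cross-check.
#'
#' @param x,y numeric vectors (complete cases are used; `n >= 4` after
#'   removal).
#' @return list with `press` and `q2_cv`.
#' @export
loo_q2 <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("leave-one-out needs at least 4 observations")
  press <- 0
  for (i in seq_len(n)) {
    xi <- x[-i]; yi <- y[-i]
    if (stats::sd(xi) == 0) {
      stop("degenerate holdout: predictor constant after removing point ", i)
    }
    cf <- stats::coef(stats::lm(yi ~ xi))
    press <- press + (y[i] - (cf[[1]] + cf[[2]] * x[i]))^2
  }
  list(press = press, q2_cv = 1 - press / sum((y - mean(y))^2))
}

#' PRESS via the hat-matrix shortcut
#'
#' For least squares, the deleted residual equals
#' `e_i / (1 - h_ii)`, so `PRESS = sum((e_i / (1 - h_ii))^2)` without any
#' refitting. Used as the independent route against the explicit refits
#' of [loo_q2()].
#'
#' @param x,y numeric vectors.
#' @return PRESS (numeric scalar).
#' @export
press_shortcut <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- !is.na(x) & !is.na(y)
  fit <- stats::lm(y[ok] ~ x[ok])
  h <- stats::hatvalues(fit)
  sum((stats::resid(fit) / (1 - h))^2)
}

#' Predict log P from a fitted calibration
#'
#' @param object an `iset_calibration` from [fit_ols()] (or any list with
#'   `a` and `b`).
#' @param x descriptor values.
#' @param ... unused.
#' @return predicted log P, `a + b * x`.
#' @export
predict.iset_calibration <- function(object, x, ...) {
  object$a + object$b * as.numeric(x)
}

#' Deviations of experimental from predicted log P
#'
#' For each record, `delta = experimental - predicted` where the
#' prediction applies the calibration line to the record's descriptor
#' value. Records without an experimental value are skipped with a
#' warning. A `delta_display` column rounds to 2 decimals, the precision
#' at which such deviations are conventionally quoted.
#'
#' @param model an `iset_calibration` (or list with `a`, `b`).
#' @param records data frame with columns `name`, `iset` and `exp_logp`.
#' @return data frame with `name`, `iset`, `exp_logp`, `predicted`,
#'   `delta`, `delta_display`.
#' @export
deviations <- function(model, records) {
  stopifnot(is.data.frame(records))
  miss <- is.na(records$exp_logp)
  if (any(miss)) {
    warning(sum(miss), " record(s) lack experimental log P and were skipped")
    records <- records[!miss, , drop = FALSE]
  }
  pred <- model$a + model$b * records$iset
  delta <- records$exp_logp - pred
  data.frame(name = records$name, iset = records$iset,
             exp_logp = records$exp_logp, predicted = pred, delta = delta,
             delta_display = round(delta, 2), stringsAsFactors = FALSE)
}

#' External test-set validation
#'
#' Regresses observed on predicted log P and predicted on observed, each
#' with a free intercept and through the origin, and summarises the
#' per-compound deviations. These are the standard external-validation
#' checks for a QSPR calibration: for a predictive model all four slopes
#' should be close to 1, the free intercepts close to 0 and the
#' coefficients of determination close to 1.
#'
#' @param observed numeric vector of experimental log P values.
#' @param predicted numeric vector of model predictions (same length,
#'   `n >= 3`).
#' @return object of class `iset_external_validation`: list with
#'   `slope_op`, `intercept_op`, `r2_op` (observed ~ predicted),
#'   `slope_po`, `intercept_po`, `r2_po`, the through-origin analogues
#'   (`slope_origin_op`, `r2_origin_op`, `slope_origin_po`,
#'   `r2_origin_po`, with `slope = sum(xy)/sum(x^2)` and squared
#'   correlation of fit to data), `deviations`, `mean_abs_dev` and
#'   `rms_dev`.
#' @export
external_validation <- function(observed, predicted) {
  observed <- as.numeric(observed); predicted <- as.numeric(predicted)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  ok <- !is.na(observed) & !is.na(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  if (length(observed) < 3L) {
    stop("external validation needs at least 3 compounds")
  }
  op <- fit_ols(predicted, observed)
  po <- fit_ols(observed, predicted)
  origin <- function(x, y) {
    slope <- sum(x * y) / sum(x^2)
    list(slope = slope,
         r2 = 1 - sum((y - slope * x)^2) / sum((y - mean(y))^2))
  }
  o_op <- origin(predicted, observed)
  o_po <- origin(observed, predicted)
  dev <- observed - predicted
  structure(
    list(slope_op = op$b, intercept_op = op$a, r2_op = op$r2,
         slope_po = po$b, intercept_po = po$a, r2_po = po$r2,
         slope_origin_op = o_op$slope, r2_origin_op = o_op$r2,
         slope_origin_po = o_po$slope, r2_origin_po = o_po$r2,
         deviations = dev, mean_abs_dev = mean(abs(dev)),
         rms_dev = sqrt(mean(dev^2)), n = length(observed)),
    class = "iset_external_validation"
  )
}

#' @export
print.iset_external_validation <- function(x, digits = 4, ...) {
  cat("external validation (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  observed ~ predicted:  Y = %.*f X %+.*f   r2 = %.*f\n",
              digits, x$slope_op, digits, x$intercept_op, digits, x$r2_op))
  cat(sprintf("    through origin:      Y = %.*f X           r2 = %.*f\n",
              digits, x$slope_origin_op, digits, x$r2_origin_op))
  cat(sprintf("  predicted ~ observed:  Y = %.*f X %+.*f   r2 = %.*f\n",
              digits, x$slope_po, digits, x$intercept_po, digits, x$r2_po))
  cat(sprintf("    through origin:      Y = %.*f X           r2 = %.*f\n",
              digits, x$slope_origin_po, digits, x$r2_origin_po))
  cat(sprintf("  mean |dev| = %.*f   RMS dev = %.*f\n",
              digits, x$mean_abs_dev, digits, x$rms_dev))
  invisible(x)
}
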