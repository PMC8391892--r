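# Leave-one-out cross-validation and the calibration metric set
# (PRESS, SECV, bias, R2, calibration line).

#' SECV from a PRESS value
#'
#' The standard error of cross-validation used throughout this package is
#' `sqrt(PRESS / n)` with `n` the calibration-set size.
#'
#' @param press Predicted residual error sum of squares, (% v/v)^2.
#' @param n Number of calibration samples.
#' @return SECV in % v/v.
#' @export
secv_from_press <- function(press, n) {
  if (any(press < 0)) stop("`press` must be >= 0")
  if (any(n < 1)) stop("`n` must be >= 1")
  sqrt(press / n)
}

#' Cross-validation metrics for predicted vs actual concentrations
#'
#' Computes the calibration quality metrics from paired actual and
#' (cross-validated) predicted concentrations:
#' PRESS `= sum((yhat - y)^2)`; SECV `= sqrt(PRESS/n)`; bias = absolute
#' value of the mean residual; R2 = squared Pearson correlation of actual
#' and predicted; and the calibration line `yhat = slope * y + intercept`
#' (predicted regressed on actual, whose slope sits just below 1 when
#' cross-validated predictions are attenuated).
#'
#' @param y_actual,y_predicted Numeric vectors of equal length (n >= 3),
#'   % v/v.
#' @return A list of class `"ftir_cv_metrics"` with elements `press`,
#'   `secv`, `bias`, `r2`, `slope`, `intercept` and `n`.
#' @export
cv_metrics <- function(y_actual, y_predicted) {
  y <- as.numeric(y_actual); yh <- as.numeric(y_predicted)
  if (length(y) != length(yh)) stop("`y_actual` and `y_predicted` lengths differ")
  n <- length(y)
  if (n < 3L) stop("at least 3 samples are required")
  if (anyNA(y) || anyNA(yh)) stop("NA values are not allowed")
  if (stats::sd(y) == 0 || stats::sd(yh) == 0)
    stop("r2 undefined: zero variance in actual or predicted values")
  res <- yh - y
  press <- sum(res^2)
  slope <- stats::cov(y, yh) / stats::var(y)
  structure(list(press = press,
                 secv = secv_from_press(press, n),
                 bias = abs(mean(res)),
                 r2 = stats::cor(y, yh)^2,
                 slope = slope,
                 intercept = mean(yh) - slope * mean(y),
                 n = n),
            class = "ftir_cv_metrics")
}

#' Leave-one-out cross-validation of a calibration model
#'
#' For each sample the model is refitted on the remaining `n - 1` samples
#' (re-centering within the fold) and used to predict the held-out sample;
#' the assembled predictions are scored with [cv_metrics()].
#'
#' @param X Numeric matrix, samples x points.
#' @param y Reference concentrations (% v/v).
#' @param method `"plsr"` or `"pcr"`.
#' @param ncomp Factors per fold; must satisfy `ncomp <= min(n-2, p)`.
#' @param sample_ids Optional sample ids (defaults to rownames of `X`).
#' @return An object of class `"ftir_cv"`: `y_actual`, `y_predicted` (input
#'   order), `sample_ids`, `method`, `ncomp`, plus all [cv_metrics()]
#'   fields.
#' @examples
#' y <- c(0, 2, 4, 8, 16, 32, 64, 100)
#' X <- outer(y, c(0.5, 1, 2)) / 100 # noiseless one-component system
#' cv <- loo_cv(X, y, method = "plsr", ncomp = 1)
#' cv$press
#' @export
loo_cv <- function(X, y, method = c("plsr", "pcr"), ncomp = 3L,
                   sample_ids = NULL) {
  method <- match.arg(method)
  d <- check_xy(X, y, ncomp, kmax_minus = 2L)
  X <- d$X; y <- d$y
  ids <- sample_ids
  if (is.null(ids)) ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(d$n))
  for (i in seq_len(d$n)) # validate folds before any fitting
    if (length(unique(y[-i])) < 2L)
      stop("fold error: leaving out sample '", ids[i],
           "' leaves zero variance in y")
  yh <- numeric(d$n)
  for (i in seq_len(d$n)) {
    fit <- fit_mvr(X[-i, , drop = FALSE], y[-i], method = method, ncomp = d$k)
    yh[i] <- predict(fit, X[i, , drop = FALSE])
  }
  m <- cv_metrics(y, yh)
  structure(c(list(y_actual = y, y_predicted = yh, sample_ids = ids,
                   method = method, ncomp = d$k), unclass(m)),
            class = "ftir_cv")
}

#' Select the number of factors by minimum LOO PRESS
#'
#' Sweeps `ncomp` from 1 to `k_max`, computing the leave-one-out PRESS for
#' each, and returns the argmin; ties are broken toward the smaller factor
#' count (the parsimonious model).
#'
#' @inheritParams loo_cv
#' @param k_max Largest factor count to consider (`<= min(n-2, p)`).
#' @return Integer: the selected number of factors.
#' @export
select_factors <- function(X, y, method = c("plsr", "pcr"), k_max) {
  method <- match.arg(method)
  d <- check_xy(X, y, k_max, kmax_minus = 2L)
  press <- vapply(seq_len(d$k), function(k)
    loo_cv(X, y, method = method, ncomp = k)$press, numeric(1))
  which.min(press) # which.min takes the first minimum: ties go to smaller k
}

#' @export
print.ftir_cv <- function(x, ...) {
  cat(sprintf(
    "<ftir_cv> %s, %d factor(s), n = %d LOO folds\n  PRESS %.4g  SECV %.4g  bias %.4g  R2 %.6f\n  calibration line: yhat = %.4f y %+.4f\n",
    toupper(x$method), x$ncomp, x$n, x$press, x$secv, x$bias, x$r2,
    x$slope, x$intercept))
  invisible(x)
}

#' Cross-validation plot (predicted vs actual)
#'
#' Scatter of LOO-predicted against actual concentrations with the identity
#' line (dashed) and the fitted calibration line.
#'
#' @param x An `ftir_cv` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ftir_cv <- function(x, ...) {
  graphics::plot(x$y_actual, x$y_predicted,
                 xlab = "actual concentration (% v/v)",
                 ylab = "predicted concentration (% v/v)",
                 main = sprintf("%s LOO cross-validation (%d factors)",
                                toupper(x$method), x$ncomp), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::abline(x$intercept, x$slope, col = "firebrick")
  invisible(x)
}
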