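# Multivariate calibration: PLS1 (NIPALS) and principal component
# regression on mean-centered spectra.

check_xy <- function(X, y, k, kmax_minus = 1L) {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X)) stop("`X` must be a numeric matrix without NA")
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("rows of `X` must align with `y`")
  if (n < 3L) stop("at least 3 calibration samples are required")
  if (length(unique(y)) < 2L) stop("`y` must span at least 2 distinct values")
  k <- as.integer(k)
  kmax <- min(n - kmax_minus, p)
  if (k < 1L || k > kmax)
    stop(sprintf("`ncomp` must be between 1 and %d for this data", kmax))
  list(X = X, y = y, n = n, p = p, k = k)
}

#' Fit a PLSR or PCR calibration model
#'
#' Fits a single-response multivariate calibration of concentration on
#' spectra, as used for quantifying an adulterant from its analysis window.
#' Both methods mean-center `X` columnwise and `y` (no variance scaling —
#' spectral channels share units) and regress through `ncomp` latent
#' factors:
#'
#' * **PLSR** (PLS1, NIPALS): per factor, the weight vector is proportional
#'   to the covariance `t(X) %*% y` (closed form for a single response),
#'   scores are `X %*% w`, X-loadings `t(X) %*% t / sum(t^2)`, and `X` and
#'   `y` are deflated before the next factor. Coefficients are assembled as
#'   `W (P'W)^-1 q`.
#' * **PCR**: singular value decomposition of centered `X`; centered `y` is
#'   regressed on the first `ncomp` score vectors (decreasing singular
#'   value, each loading signed so its largest-magnitude element is
#'   positive) and mapped back to the original variables.
#'
#' At `ncomp = min(n-1, p)` with full-rank `X`, both reduce to ordinary
#' least squares on the centered data.
#'
#' @param X Numeric matrix, samples x spectral points (preprocessed
#'   absorbances).
#' @param y Numeric vector of reference concentrations (% v/v).
#' @param method `"plsr"` or `"pcr"`.
#' @param ncomp Number of latent factors, `1 <= ncomp <= min(n-1, p)`.
#'   Default 3, the usual choice for single-adulterant windows.
#' @return An object of class `"ftir_mvr"`: list with `method`, `ncomp`,
#'   `x_mean`, `y_mean`, `coefficients` (length p, on centered data),
#'   `scores`, `loadings`, `weights` (PLSR only), `explained_variance_ratio`
#'   (PCR only), `fitted.values` and `call`.
#' @seealso [predict.ftir_mvr()], [loo_cv()], [select_factors()]
#' @examples
#' set.seed(42)
#' X <- outer(c(0, 2, 4, 8, 16, 32, 64, 100), sin(1:20 / 3)) / 100
#' y <- c(0, 2, 4, 8, 16, 32, 64, 100)
#' fit <- fit_mvr(X, y, method = "plsr", ncomp = 1)
#' round(fitted(fit), 6)
#' @export
fit_mvr <- function(X, y, method = c("plsr", "pcr"), ncomp = 3L) {
  method <- match.arg(method)
  d <- check_xy(X, y, ncomp, kmax_minus = 1L)
  X <- d$X; y <- d$y; k <- d$k
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean); yc <- y - y_mean

  if (method == "plsr") {
    W <- P <- matrix(0, d$p, k)
    Tm <- matrix(0, d$n, k)
    q <- numeric(k)
    Xd <- Xc; yd <- yc
    for (a in seq_len(k)) {
      w <- drop(crossprod(Xd, yd))
      wn <- sqrt(sum(w^2))
      if (wn == 0) stop("zero covariance: cannot extract factor ", a)
      w <- w / wn
      t <- drop(Xd %*% w)
      tt <- sum(t^2)
      P[, a] <- drop(crossprod(Xd, t)) / tt
      q[a] <- sum(yd * t) / tt
      W[, a] <- w; Tm[, a] <- t
      Xd <- Xd - tcrossprod(t, P[, a])
      yd <- yd - q[a] * t
    }
    B <- drop(W %*% solve(crossprod(P, W), q))
    obj <- list(method = "plsr", ncomp = k, x_mean = x_mean, y_mean = y_mean,
                coefficients = B, scores = Tm, loadings = P, weights = W,
                q = q)
  } else {
    sv <- svd(Xc)
    pos <- sv$d > max(d$n, d$p) * .Machine$double.eps * sv$d[1]
    if (k > sum(pos))
      stop(sprintf("`ncomp` = %d exceeds the rank (%d) of centered X",
                   k, sum(pos)))
    V <- sv$v[, seq_len(k), drop = FALSE]
    U <- sv$u[, seq_len(k), drop = FALSE]
    dg <- sv$d[seq_len(k)]
    for (a in seq_len(k)) { # sign convention: largest |loading| positive
      j <- which.max(abs(V[, a]))
      if (V[j, a] < 0) { V[, a] <- -V[, a]; U[, a] <- -U[, a] }
    }
    Tm <- U * rep(dg, each = d$n)
    gamma <- drop(crossprod(Tm, yc)) / dg^2 # scores are orthogonal
    B <- drop(V %*% gamma)
    obj <- list(method = "pcr", ncomp = k, x_mean = x_mean, y_mean = y_mean,
                coefficients = B, scores = Tm, loadings = V,
                explained_variance_ratio = sv$d^2 / sum(sv$d^2))
  }
  obj$fitted.values <- drop(y_mean + Xc %*% obj$coefficients)
  obj$residuals <- y - obj$fitted.values
  obj$y <- y
  obj$call <- match.call()
  class(obj) <- "ftir_mvr"
  obj
}

#' Predict concentrations from a fitted calibration model
#'
#' Applies `y_mean + (X_new - x_mean) %*% coefficients`. Predictions are not
#' clipped to the 0-100 % v/v range.
#'
#' @param object An `ftir_mvr` fit.
#' @param newdata Numeric matrix (or single row vector) with the same number
#'   of spectral points as the training matrix.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations (% v/v).
#' @export
predict.ftir_mvr <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop(sprintf("`newdata` has %d columns; model expects %d",
                 ncol(newdata), length(object$x_mean)))
  drop(object$y_mean +
         sweep(newdata, 2L, object$x_mean) %*% object$coefficients)
}

#' @export
coef.ftir_mvr <- function(object, ...) object$coefficients

#' @export
fitted.ftir_mvr <- function(object, ...) object$fitted.values

#' @export
residuals.ftir_mvr <- function(object, ...) object$residuals

#' @export
print.ftir_mvr <- function(x, ...) {
  cat(sprintf("<ftir_mvr> %s calibration, %d factor(s), %d samples x %d points\n",
              toupper(x$method), x$ncomp, nrow(x$scores),
              length(x$coefficients)))
  invisible(x)
}

#' @export
summary.ftir_mvr <- function(object, ...) {
  rss <- sum(object$residuals^2)
  tss <- sum((object$y - mean(object$y))^2)
  cat(sprintf("%s calibration model\n", toupper(object$method)))
  cat(sprintf("  samples: %d   spectral points: %d   factors: %d\n",
              nrow(object$scores), length(object$coefficients), object$ncomp))
  cat(sprintf("  in-sample RMSE: %.4g %% v/v   R2: %.4f\n",
              sqrt(rss / length(object$y)), 1 - rss / tss))
  if (object$method == "pcr")
    cat("  explained variance ratio (retained): ",
        paste(sprintf("%.3f",
                      object$explained_variance_ratio[seq_len(object$ncomp)]),
              collapse = " "), "\n", sep = "")
  invisible(object)
}
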