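# Spectral preprocessing: Savitzky-Golay derivatives and vector
# normalization, composed into the matrix-assembly pipeline.

#' Preprocessing specification
#'
#' @param derivative_order 0 (raw), 1 or 2.
#' @param sg_window Savitzky-Golay window length in points; odd and larger
#'   than `sg_polyorder`. Default 9.
#' @param sg_polyorder Polynomial order of the local fit. Default 3.
#' @param normalize Apply vector normalization after windowing?
#' @return A list of class `"preprocess_spec"`.
#' @export
preprocess_spec <- function(derivative_order = 0L, sg_window = 9L,
                            sg_polyorder = 3L, normalize = FALSE) {
  derivative_order <- as.integer(derivative_order)
  sg_window <- as.integer(sg_window); sg_polyorder <- as.integer(sg_polyorder)
  if (!derivative_order %in% 0:2) stop("`derivative_order` must be 0, 1 or 2")
  if (sg_window %% 2L == 0L || sg_window <= sg_polyorder)
    stop("`sg_window` must be odd and greater than `sg_polyorder`")
  if (derivative_order > 0L && derivative_order > sg_polyorder)
    stop("`sg_polyorder` must be >= `derivative_order`")
  structure(list(derivative_order = derivative_order, sg_window = sg_window,
                 sg_polyorder = sg_polyorder, normalize = isTRUE(normalize)),
            class = "preprocess_spec")
}

# derivative weights for a local polynomial fit at offsets `x` (signed,
# physical units), evaluated at 0: row `order+1` of factorial(order) * pinv(V)
sg_weights <- function(x, polyorder, order) {
  V <- outer(x, 0:polyorder, `^`)
  # (V'V)^-1 V' via QR for stability
  coefs <- qr.solve(qr(V), diag(length(x)))
  factorial(order) * coefs[order + 1L, ]
}

#' Savitzky-Golay derivative of a spectrum
#'
#' Differentiates with respect to the wavenumber axis by local least-squares
#' polynomial fits on a sliding window (the classical Savitzky-Golay
#' scheme). The grid must be uniformly spaced; the signed step is honoured,
#' so the derivative is physical (`d/dnu` in AU/cm^-1 per order) on the
#' canonical descending grid, not an index-based difference. At the
#' `(window-1)/2` points nearest each end the polynomial is fitted on the
#' truncated one-sided window instead of being extrapolated.
#'
#' @param spectrum A [spectrum()] on a uniform grid.
#' @param order Derivative order (0, 1 or 2); 0 returns the smoothed
#'   spectrum.
#' @param window Window length in points (odd, > `polyorder`, <= spectrum
#'   length). Default 9.
#' @param polyorder Local polynomial order (>= `order`). Default 3.
#' @return A [spectrum()] on the same grid with differentiated values.
#' @export
savgol_derivative <- function(spectrum, order, window = 9L, polyorder = 3L) {
  if (!is_spectrum(spectrum)) stop("`spectrum` must be a spectrum object")
  spec <- preprocess_spec(max(order, 0L), window, polyorder,
                          normalize = FALSE) # reuse validation
  order <- as.integer(order)
  if (!order %in% 0:2) stop("`order` must be 0, 1 or 2")
  if (order > polyorder) stop("`polyorder` must be >= `order`")
  wn <- spectrum$wavenumbers; y <- spectrum$absorbance
  n <- length(y)
  if (window > n) stop("`window` exceeds the spectrum length")
  steps <- diff(wn)
  h <- steps[1]
  if (max(abs(steps - h)) > 1e-6 * abs(h))
    stop("non-uniform grid: Savitzky-Golay differentiation needs uniform spacing")
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  # interior: one convolution kernel
  if (n >= window) {
    w <- sg_weights(h * (-half:half), polyorder, order)
    idx <- seq.int(half + 1L, n - half)
    for (k in seq_len(window))
      out[idx] <- out[idx] + w[k] * y[idx + (k - half - 1L)]
  }
  # edges: truncated one-sided windows
  for (i in if (half > 0L) c(seq_len(half), seq.int(n - half + 1L, n)) else integer(0)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    po <- min(polyorder, hi - lo) # degenerate guard for tiny spectra
    if (po < order) stop("window too short near the spectrum edge")
    w <- sg_weights(h * (seq.int(lo, hi) - i), po, order)
    out[i] <- sum(w * y[lo:hi])
  }
  spectrum(spectrum$sample_id, wn, out)
}

#' Vector normalization
#'
#' Subtracts the mean and scales the centered vector to unit Euclidean norm
#' (the convention of common FTIR instrument software). The result is
#' dimensionless, has mean zero and norm one, and is invariant to scaling of
#' the input.
#'
#' @param x A [spectrum()] or a numeric vector.
#' @return Object of the same kind as `x`, normalized.
#' @export
vector_normalize <- function(x) UseMethod("vector_normalize")

#' @export
vector_normalize.numeric <- function(x) {
  v <- x - mean(x)
  nrm <- sqrt(sum(v^2))
  if (nrm < .Machine$double.eps * length(x) * max(1, abs(mean(x))) ||
      nrm == 0)
    stop("normalization error: spectrum is constant (zero centered norm)")
  v / nrm
}

#' @export
vector_normalize.spectrum <- function(x) {
  spectrum(x$sample_id, x$wavenumbers, vector_normalize(x$absorbance))
}

#' Assemble a preprocessed data matrix from spectra
#'
#' Applies, per spectrum: the Savitzky-Golay derivative (if any) on the full
#' grid, then window extraction, then vector normalization (if requested)
#' over the concatenated windowed points. Differentiating before windowing
#' avoids edge artifacts inside the analysis windows; normalizing after
#' windowing normalizes over the selected frequency ranges only.
#'
#' @param spectra List of [spectrum()] objects on one shared grid.
#' @param spec A [preprocess_spec()].
#' @param windows Optional window list as in [extract_windows()]; `NULL`
#'   keeps the full grid.
#' @return Numeric matrix, one row per spectrum (rownames = sample ids),
#'   one column per retained grid point (colnames = wavenumbers).
#' @export
apply_pipeline <- function(spectra, spec = preprocess_spec(), windows = NULL) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  if (!length(spectra)) stop("no spectra supplied")
  if (!inherits(spec, "preprocess_spec"))
    stop("`spec` must be a preprocess_spec object")
  assert_shared_grid(spectra)
  rows <- lapply(spectra, function(s) {
    if (spec$derivative_order > 0L)
      s <- savgol_derivative(s, spec$derivative_order, spec$sg_window,
                             spec$sg_polyorder)
    if (!is.null(windows)) s <- extract_windows(s, windows)
    v <- s$absorbance
    if (spec$normalize) v <- vector_normalize(v)
    stats::setNames(v, format(s$wavenumbers, trim = TRUE))
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(spectra, `[[`, character(1), "sample_id")
  X
}
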