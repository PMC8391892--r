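#' Construct a spectrum object
#'
#' A spectrum is a set of absorbance values on a strictly monotonic wavenumber
#' grid. The canonical storage order is descending wavenumber (4000 down to
#' 600 cm^-1, the usual mid-infrared plotting convention); input in ascending
#' order is re-sorted on construction.
#'
#' @param sample_id Character scalar identifying the sample.
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, strictly
#'   monotonic, length >= 2.
#' @param absorbance Numeric vector of absorbance values (AU), same length as
#'   `wavenumbers`.
#' @return An object of class `"spectrum"`: a list with elements `sample_id`,
#'   `wavenumbers` (descending) and `absorbance`.
#' @examples
#' s <- spectrum("REO1", c(4000, 3998, 3996), c(0.1, 0.12, 0.11))
#' s$wavenumbers
#' @export
spectrum <- function(sample_id, wavenumbers, absorbance) {
  if (!is.character(sample_id) || length(sample_id) != 1L || is.na(sample_id))
    stop("`sample_id` must be a single character string")
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance))
    stop("`wavenumbers` and `absorbance` must have equal length")
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least 2 points")
  if (anyNA(wavenumbers) || anyNA(absorbance))
    stop("NA values are not allowed in a spectrum")
  d <- diff(wavenumbers)
  if (any(d == 0))
    stop("duplicate wavenumbers in grid")
  if (!(all(d > 0) || all(d < 0)))
    stop("wavenumber grid must be strictly monotonic")
  if (all(d > 0)) { # normalize to canonical descending order
    o <- order(wavenumbers, decreasing = TRUE)
    wavenumbers <- wavenumbers[o]
    absorbance <- absorbance[o]
  }
  structure(list(sample_id = sample_id, wavenumbers = wavenumbers,
                 absorbance = absorbance),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %d points, %.6g to %.6g cm^-1, A in [%.4g, %.4g]\n",
              x$sample_id, length(x$wavenumbers),
              x$wavenumbers[1], x$wavenumbers[length(x$wavenumbers)],
              min(x$absorbance), max(x$absorbance)))
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$wavenumbers)

is_spectrum <- function(x) inherits(x, "spectrum")

# shared grid check used by several operations
assert_shared_grid <- function(spectra, tol = 0) {
  g <- spectra[[1]]$wavenumbers
  for (s in spectra[-1]) {
    if (length(s$wavenumbers) != length(g) ||
        any(abs(s$wavenumbers - g) > tol))
      stop("spectra do not share an identical wavenumber grid")
  }
  g
}

#' The default simulation wavenumber grid
#'
#' Descending grid from `high` to `low` in steps of `step` cm^-1. The default
#' (4000 to 600 by 2 cm^-1; 1701 points) approximates the point spacing of a
#' mid-infrared instrument operated at 4 cm^-1 resolution.
#'
#' @param high,low Grid end points in cm^-1.
#' @param step Point spacing in cm^-1 (positive).
#' @return Numeric vector of descending wavenumbers.
#' @export
default_grid <- function(high = 4000, low = 600, step = 2) {
  if (step <= 0) stop("`step` must be positive")
  if (high <= low) stop("`high` must exceed `low`")
  seq(high, low, by = -step)
}

#' Read spectra from a wide CSV table
#'
#' The interchange format is a wide CSV whose first column is named
#' `wavenumber` and whose remaining columns each hold one sample's absorbance
#' values (column header = sample id). Grids stored in ascending order are
#' reordered to the canonical descending convention.
#'
#' @param path Path to the CSV file.
#' @return Named list of [spectrum()] objects, one per sample column, all
#'   sharing the file's grid.
#' @seealso [write_spectra_table()]
#' @export
read_spectra_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("spectra table needs a 'wavenumber' column plus at least one sample column")
  if (names(df)[1] != "wavenumber")
    stop("first column must be named 'wavenumber', found '", names(df)[1], "'")
  if (nrow(df) < 2L)
    stop("grid error: fewer than 2 rows in ", path)
  num <- vector("list", ncol(df))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (anyNA(v)) {
      row <- if (length(bad)) bad[1] else which(is.na(v))[1]
      stop(sprintf("parse error: non-numeric value in column '%s', data row %d",
                   names(df)[j], row))
    }
    num[[j]] <- v
  }
  wn <- num[[1]]
  if (anyDuplicated(wn))
    stop("grid error: duplicate wavenumber values in ", path)
  out <- lapply(seq.int(2L, ncol(df)), function(j)
    spectrum(names(df)[j], wn, num[[j]]))
  names(out) <- names(df)[-1]
  out
}

#' Write spectra to a wide CSV table
#'
#' Inverse of [read_spectra_table()]: all spectra must share one grid; values
#' are written at full double precision so a read/write round trip is the
#' identity to well below 1e-9 relative error.
#'
#' @param spectra List of [spectrum()] objects on one common grid.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spectra_table <- function(spectra, path) {
  if (length(spectra) == 0L)
    stop("cannot write an empty list of spectra")
  if (!all(vapply(spectra, is_spectrum, logical(1))))
    stop("`spectra` must be a list of spectrum objects")
  g <- assert_shared_grid(spectra)
  cols <- c(list(wavenumber = g),
            stats::setNames(lapply(spectra, `[[`, "absorbance"),
                            vapply(spectra, `[[`, character(1), "sample_id")))
  txt <- do.call(cbind, lapply(cols, function(v) sprintf("%.17g", v)))
  colnames(txt) <- names(cols)
  utils::write.csv(as.data.frame(txt, check.names = FALSE), path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Resample a spectrum onto a new wavenumber grid
#'
#' Linear interpolation between the two nearest source points; exact at grid
#' points that coincide with source points. Extrapolation is refused.
#'
#' @param spectrum A [spectrum()] object.
#' @param grid Numeric vector of target wavenumbers, all inside the source
#'   span.
#' @return A [spectrum()] on `grid` (stored descending).
#' @export
resample_to_grid <- function(spectrum, grid) {
  if (!is_spectrum(spectrum)) stop("`spectrum` must be a spectrum object")
  grid <- as.numeric(grid)
  lo <- min(spectrum$wavenumbers); hi <- max(spectrum$wavenumbers)
  if (any(grid < lo) || any(grid > hi))
    stop(sprintf("extrapolation error: target grid exceeds source span [%g, %g]",
                 lo, hi))
  a <- stats::approx(rev(spectrum$wavenumbers), rev(spectrum$absorbance),
                     xout = grid, method = "linear", ties = "ordered")$y
  spectrum(spectrum$sample_id, grid, a)
}

#' Define a wavenumber window
#'
#' @param high,low Window bounds in cm^-1 with `high > low`; both bounds are
#'   inclusive when selecting grid points.
#' @return Numeric vector `c(high, low)` of class `"wn_window"`.
#' @export
wn_window <- function(high, low) {
  if (!is.numeric(high) || !is.numeric(low) || length(high) != 1L ||
      length(low) != 1L || is.na(high) || is.na(low))
    stop("window bounds must be numeric scalars")
  if (high <= low) stop("window `high` must exceed `low`")
  structure(c(high = high, low = low), class = "wn_window")
}

as_window_list <- function(windows) {
  if (inherits(windows, "wn_window")) windows <- list(windows)
  lapply(windows, function(w) {
    if (inherits(w, "wn_window")) return(w)
    if (is.numeric(w) && length(w) == 2L) return(wn_window(max(w), min(w)))
    stop("each window must be a wn_window or a numeric pair c(high, low)")
  })
}

assert_nonoverlapping <- function(windows) {
  if (length(windows) < 2L) return(invisible(windows))
  m <- do.call(rbind, lapply(windows, unclass))
  o <- order(m[, "high"], decreasing = TRUE)
  m <- m[o, , drop = FALSE]
  for (i in seq_len(nrow(m) - 1L))
    if (m[i, "low"] <= m[i + 1L, "high"])
      stop("windows overlap: [", m[i + 1L, "high"], ", ", m[i + 1L, "low"],
           "] and [", m[i, "high"], ", ", m[i, "low"], "]")
  invisible(windows)
}

#' Extract spectral windows
#'
#' Restricts a spectrum to one or more non-overlapping wavenumber windows
#' (bounds inclusive). The result is the concatenation of the selected points
#' in descending wavenumber order; no interpolation is performed, so the
#' output grid is a subset of the input grid.
#'
#' @param spectrum A [spectrum()] object.
#' @param windows A [wn_window()], a list of them, or a list of numeric
#'   `c(high, low)` pairs.
#' @return A [spectrum()] restricted to the selected points.
#' @export
extract_windows <- function(spectrum, windows) {
  if (!is_spectrum(spectrum)) stop("`spectrum` must be a spectrum object")
  windows <- as_window_list(windows)
  assert_nonoverlapping(windows)
  keep <- rep(FALSE, length(spectrum$wavenumbers))
  for (w in windows) {
    sel <- spectrum$wavenumbers >= w["low"] & spectrum$wavenumbers <= w["high"]
    if (!any(sel))
      stop(sprintf("empty selection: window [%g, %g] contains no grid points",
                   w["high"], w["low"]))
    keep <- keep | sel
  }
  spectrum(spectrum$sample_id, spectrum$wavenumbers[keep],
           spectrum$absorbance[keep])
}

#' Read a minimal JCAMP-DX spectrum
#'
#' Supports only the tabular `##XYDATA=(X++(Y..Y))` form with plain AFFN
#' numerals: an evenly spaced grid described by `##FIRSTX`, `##LASTX` and
#' `##NPOINTS`, with optional `##XFACTOR`/`##YFACTOR` scaling. Compressed
#' (SQZ/DIF/DUP) ordinates and any other data class raise an
#' unsupported-dialect error.
#'
#' @param path Path to a JCAMP-DX file.
#' @param sample_id Sample id for the returned spectrum; defaults to the
#'   `##TITLE` record or the file name.
#' @return A [spectrum()] object.
#' @export
read_jcamp <- function(path, sample_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(paste0("^##", name, "="), lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1]))
  }
  xy <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (!length(xy))
    stop("unsupported JCAMP-DX dialect: no ##XYDATA record")
  form <- gsub("\\s", "", toupper(sub("^##XYDATA=", "", lines[xy[1]],
                                      ignore.case = TRUE)))
  if (form != "(X++(Y..Y))")
    stop("unsupported JCAMP-DX dialect: XYDATA form '", form, "'")
  firstx <- as.numeric(ldr("FIRSTX")); lastx <- as.numeric(ldr("LASTX"))
  npt <- as.numeric(ldr("NPOINTS"))
  if (!length(firstx) || !length(lastx) || !length(npt) ||
      is.na(firstx) || is.na(lastx) || is.na(npt))
    stop("unsupported JCAMP-DX dialect: FIRSTX/LASTX/NPOINTS required")
  yf <- ldr("YFACTOR")
  yf <- if (is.null(yf)) 1 else as.numeric(yf)
  end <- grep("^##END", lines, ignore.case = TRUE)
  end <- if (length(end)) min(end[end > xy[1]]) else length(lines) + 1L
  body <- lines[seq.int(xy[1] + 1L, end - 1L)]
  body <- body[nzchar(trimws(body))]
  ys <- numeric(0)
  for (ln in body) {
    tok <- strsplit(trimws(ln), "[,[:space:]]+")[[1]]
    if (any(grepl("[^0-9eE+.-]", tok)) || anyNA(suppressWarnings(as.numeric(tok))))
      stop("unsupported JCAMP-DX dialect: non-AFFN ordinates in '", ln, "'")
    ys <- c(ys, as.numeric(tok)[-1]) # first token is the line's X value
  }
  if (length(ys) != npt)
    stop(sprintf("JCAMP-DX NPOINTS mismatch: declared %d, found %d",
                 as.integer(npt), length(ys)))
  wn <- seq(firstx, lastx, length.out = npt) # FIRSTX/LASTX are true values
  if (is.null(sample_id)) {
    sample_id <- ldr("TITLE")
    if (is.null(sample_id) || !nzchar(sample_id)) sample_id <- basename(path)
  }
  spectrum(sample_id, wn, ys * yf)
}
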