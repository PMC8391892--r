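# Parametric band models standing in for measured pure-component spectra.

#' Evaluate a single absorption band on a grid
#'
#' Gaussian: `a * exp(-4*log(2) * (nu - c)^2 / w^2)`; Lorentzian:
#' `a * (w/2)^2 / ((nu - c)^2 + (w/2)^2)`. In both shapes `w` is the full
#' width at half maximum, so the profile equals `a/2` at `c +/- w/2` and
#' peaks at `a` when the center lies on the grid.
#'
#' @param center Band center in cm^-1.
#' @param amplitude Peak height in AU (>= 0).
#' @param fwhm Full width at half maximum in cm^-1 (> 0).
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @param grid Numeric vector of wavenumbers at which to evaluate.
#' @return Numeric vector of absorbance contributions, same length as `grid`.
#' @export
band_profile <- function(center, amplitude, fwhm, shape = "gaussian", grid) {
  shape <- match.arg(shape, c("gaussian", "lorentzian"))
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  if (fwhm <= 0) stop("`fwhm` must be > 0")
  if (center > 4000 || center < 600)
    stop("`center` must lie within the 4000-600 cm^-1 range")
  d <- grid - center
  if (shape == "gaussian") {
    amplitude * exp(-4 * log(2) * d^2 / fwhm^2)
  } else {
    hw2 <- (fwhm / 2)^2
    amplitude * hw2 / (d^2 + hw2)
  }
}

band_table <- function(center, amplitude, fwhm, shape = "gaussian") {
  data.frame(center = center, amplitude = amplitude, fwhm = fwhm,
             shape = shape, stringsAsFactors = FALSE)
}

#' Default pure-component band library
#'
#' Parametric stand-ins for the four pure components of the adulteration
#' study: rose essential oil (REO), geranium oil (GEO), palmarosa oil (PEO)
#' and phenylethyl alcohol (PEOH).
#'
#' REO carries its 13 characteristic mid-infrared bands (3345, 2958, 2922,
#' 2853, 1669, 1514, 1452, 1377, 1260, 1234, 1056, 1005 and 829 cm^-1); only
#' the positions are instrument-anchored, while amplitudes (0.1-0.6 AU, the
#' C-H stretches near 2922/2853 and the fingerprint bands at 1005/1056
#' strongest) and widths (10-40 cm^-1) are plausible values for neat
#' essential-oil ATR spectra. Each adulterant shares an oil-like backbone but
#' contributes at least one band with strong positive contrast against REO
#' inside its quantification window: PEO at 1672 cm^-1 (window 1700-1600),
#' GEO at 1170 cm^-1 (window 1218-1130), and PEOH the monosubstituted
#' aromatic pattern (3029, 1496, 746 and 700 cm^-1) whose 700 cm^-1 band
#' sits inside the 710-690 window.
#'
#' @param brand_jitter_cv Coefficient of variation of the per-brand lognormal
#'   amplitude jitter applied by [component_spectrum()]; emulates slight
#'   brand-to-brand intensity differences. Default 0.05.
#' @return An object of class `"component_library"`: list with `components`
#'   (named list of band data frames) and `brand_jitter_cv`.
#' @export
default_component_library <- function(brand_jitter_cv = 0.05) {
  reo <- band_table(
    center    = c(3345, 2958, 2922, 2853, 1669, 1514, 1452, 1377,
                  1260, 1234, 1056, 1005,  829),
    amplitude = c(0.15, 0.35, 0.60, 0.45, 0.25, 0.12, 0.32, 0.30,
                  0.20, 0.18, 0.48, 0.55, 0.22),
    fwhm      = c(  40,   14,   14,   14,   16,   10,   14,   12,
                    14,   14,   18,   14,   12))
  # palmarosa: terpene oil sharing the rose-oil backbone (geraniol is a
  # major constituent of both); marker band is the stronger C=C near 1672
  peo <- band_table(
    center    = c(3340, 2920, 2855, 1672, 1452, 1377, 1260, 1110, 1005,  836),
    amplitude = c(0.14, 0.58, 0.42, 0.50, 0.28, 0.28, 0.16, 0.22, 0.45, 0.18),
    fwhm      = c(  40,   14,   14,   16,   14,   12,   14,   16,   14,   12))
  # geranium: citronellol/geraniol rich, again close to rose oil; marker is
  # the C-O stretch near 1170
  geo <- band_table(
    center    = c(3360, 2922, 2857, 1670, 1452, 1378, 1170, 1056, 1005,  830),
    amplitude = c(0.15, 0.57, 0.43, 0.18, 0.30, 0.28, 0.40, 0.42, 0.42, 0.18),
    fwhm      = c(  40,   14,   14,   16,   14,   12,   14,   18,   14,   12))
  # phenylethyl alcohol: an aromatic alcohol, chemically unlike the terpene
  # oils — monosubstituted-ring C-H 3029, sharp ring modes 1604/1496, C-O
  # 1045, and the intense out-of-plane pair 746/700 typical of a
  # monosubstituted benzene
  peoh <- band_table(
    center    = c(3330, 3029, 2930, 2870, 1604, 1496, 1453, 1045,  746,  700),
    amplitude = c(0.30, 0.28, 0.32, 0.22, 0.60, 1.40, 1.40, 0.60, 2.10, 2.40),
    fwhm      = c(  36,   16,   14,   14,   10,   10,   12,   16,   10,   10))
  structure(list(components = list(REO = reo, GEO = geo, PEO = peo,
                                   PEOH = peoh),
                 brand_jitter_cv = brand_jitter_cv),
            class = "component_library")
}

validate_library <- function(library) {
  if (!inherits(library, "component_library") ||
      !is.list(library$components))
    stop("`library` must be a component_library object")
  for (nm in names(library$components)) {
    b <- library$components[[nm]]
    if (any(b$amplitude < 0) || any(b$fwhm <= 0) ||
        any(b$center > 4000 | b$center < 600))
      stop("invalid band parameters for component '", nm, "'")
  }
  if (library$brand_jitter_cv < 0) stop("brand_jitter_cv must be >= 0")
  invisible(library)
}

#' Write / read a component library as YAML
#'
#' The library is serialized as a mapping from component name to a list of
#' band records (center, amplitude, fwhm, shape) plus the jitter CV.
#'
#' @param library A `component_library`.
#' @param path File path.
#' @return `read_component_library()` returns a `component_library`;
#'   `write_component_library()` returns `path` invisibly.
#' @export
write_component_library <- function(library, path) {
  validate_library(library)
  doc <- list(brand_jitter_cv = library$brand_jitter_cv,
              components = lapply(library$components, function(b)
                lapply(seq_len(nrow(b)), function(i) as.list(b[i, ]))))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_component_library
#' @export
read_component_library <- function(path) {
  doc <- yaml::read_yaml(path)
  comps <- lapply(doc$components, function(bands)
    do.call(rbind, lapply(bands, function(b)
      band_table(b$center, b$amplitude, b$fwhm,
                 if (is.null(b$shape)) "gaussian" else b$shape))))
  validate_library(structure(list(components = comps,
                                  brand_jitter_cv = doc$brand_jitter_cv),
                             class = "component_library"))
}

# run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic small-integer seed for a brand name under a dataset seed
brand_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  (as.integer(seed) %% 1000003L) * 2039L + (h %% 1000003L)
}

#' Synthesize a pure-component spectrum
#'
#' Sums the component's band profiles on `grid`. When `brand_seed` is given,
#' every band amplitude is multiplied by an independent lognormal factor with
#' mean 1 and coefficient of variation `library$brand_jitter_cv`,
#' deterministically in the seed — the same seed always reproduces the same
#' "brand" of the component.
#'
#' @param library A `component_library` (see [default_component_library()]).
#' @param name Component name present in the library.
#' @param grid Wavenumber grid (descending; see [default_grid()]).
#' @param brand_seed Integer seed for brand jitter, or `NULL` for the nominal
#'   spectrum.
#' @return A [spectrum()] named after the component.
#' @export
component_spectrum <- function(library, name, grid, brand_seed = NULL) {
  validate_library(library)
  if (!name %in% names(library$components))
    stop("unknown component '", name, "'")
  b <- library$components[[name]]
  amp <- b$amplitude
  if (!is.null(brand_seed) && library$brand_jitter_cv > 0) {
    cv <- library$brand_jitter_cv
    sdlog <- sqrt(log(1 + cv^2))
    fac <- with_seed(brand_seed,
                     stats::rlnorm(nrow(b), meanlog = -sdlog^2 / 2,
                                   sdlog = sdlog))
    amp <- amp * fac
  }
  a <- numeric(length(grid))
  for (i in seq_len(nrow(b)))
    a <- a + band_profile(b$center[i], amp[i], b$fwhm[i], b$shape[i], grid)
  spectrum(name, grid, a)
}
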