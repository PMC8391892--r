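# Spiked-sample design and synthetic dataset generation.

ADULTERATION_LEVELS <- c(0, 2, 4, 8, 16, 32, 64, 100)

PAIRINGS <- data.frame(
  adulterant_brand = c("PEO1", "PEO2", "PEO3", "GEO1", "GEO2", "GEO3", "PEOH"),
  base_brand       = c("REO1", "REO2", "REO3", "REO1", "REO2", "REO3", "REO1"),
  stringsAsFactors = FALSE)

#' Volumetric Beer-Lambert mixing of two spectra
#'
#' Models the absorbance of a blend as the volume-fraction weighted sum of
#' the component absorbances:
#' `A = (1 - level/100) * A_base + (level/100) * A_adulterant`.
#'
#' @param base,adulterant [spectrum()] objects on the same grid.
#' @param level Adulteration level in percent v/v, in `[0, 100]`.
#' @param sample_id Id for the mixture; defaults to the base id.
#' @return A [spectrum()] on the shared grid.
#' @export
mix_spectra <- function(base, adulterant, level, sample_id = base$sample_id) {
  if (!is_spectrum(base) || !is_spectrum(adulterant))
    stop("`base` and `adulterant` must be spectrum objects")
  assert_shared_grid(list(base, adulterant))
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level < 0 || level > 100)
    stop("`level` must be a single value in [0, 100] % v/v")
  f <- level / 100
  spectrum(sample_id, base$wavenumbers,
           (1 - f) * base$absorbance + f * adulterant$absorbance)
}

#' Enumerate the spiked-sample design
#'
#' Seven oil/adulterant pairings — PEO1/REO1, PEO2/REO2, PEO3/REO3,
#' GEO1/REO1, GEO2/REO2, GEO3/REO3 and PEOH/REO1 — each at the eight
#' adulteration levels 0, 2, 4, 8, 16, 32, 64 and 100 % v/v. Rows with an
#' intermediate level (neither 0 nor 100) are flagged `spiked`; there are 42
#' of them (7 pairings x 6 levels). The enumeration is deterministic and
#' order-stable.
#'
#' @return A data frame with columns `sample_id`, `series` (e.g.
#'   `"PEO1 REO1"`), `base_brand`, `adulterant` (`"none"` for level-0 rows),
#'   `level` (% v/v) and `spiked` (logical).
#' @export
generate_design <- function() {
  rows <- do.call(rbind, lapply(seq_len(nrow(PAIRINGS)), function(i) {
    ad <- PAIRINGS$adulterant_brand[i]; base <- PAIRINGS$base_brand[i]
    data.frame(
      sample_id = sprintf("%s-%s-%03d", ad, base, ADULTERATION_LEVELS),
      series = paste(ad, base),
      base_brand = base,
      adulterant = ifelse(ADULTERATION_LEVELS == 0, "none", ad),
      level = ADULTERATION_LEVELS,
      spiked = !(ADULTERATION_LEVELS %in% c(0, 100)),
      stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

# component type (library key) behind a brand code such as "PEO2" or "PEOH"
brand_component <- function(brand) sub("[0-9]+$", "", brand)

#' Generate a synthetic spiked-sample dataset
#'
#' For every design row the (brand-jittered) base-oil and adulterant spectra
#' are blended with [mix_spectra()] at the row's level; an optional linear
#' baseline and i.i.d. zero-mean Gaussian noise (per point, sd = `noise_sd`)
#' are then added. `noise_sd` is the noise level of the delivered spectrum,
#' i.e. after any on-instrument scan averaging. Brand jitter is seeded per
#' brand name, so e.g. REO1 has the same band intensities in every series of
#' a given dataset. The whole dataset is a deterministic function of `seed`.
#'
#' @param library A `component_library`; see [default_component_library()].
#' @param design Data frame as returned by [generate_design()].
#' @param grid Wavenumber grid; default [default_grid()].
#' @param noise_sd Per-point Gaussian noise sd in AU (>= 0). Default 0.003.
#' @param baseline_slope Half-range of the per-sample random baseline slope
#'   in AU per cm^-1; each sample receives a linear baseline
#'   `s * (nu - mean(nu))` with `s` uniform on
#'   `[-baseline_slope, baseline_slope]`. Default 0 (no baseline).
#' @param seed Integer seed controlling jitter, baselines and noise.
#' @return An object of class `"synthetic_dataset"`: list with `spectra`
#'   (named list of [spectrum()]), `reference` (the design data frame) and
#'   `seed`.
#' @export
generate_dataset <- function(library = default_component_library(),
                             design = generate_design(),
                             grid = default_grid(),
                             noise_sd = 0.003,
                             baseline_slope = 0,
                             seed = 1L) {
  validate_library(library)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (baseline_slope < 0) stop("`baseline_slope` must be >= 0")
  need <- c("sample_id", "series", "base_brand", "level")
  if (!all(need %in% names(design)))
    stop("`design` must contain columns: ", paste(need, collapse = ", "))

  # one jittered spectrum per brand, seeded by brand name under `seed`
  ad_brand <- sub(" .*$", "", design$series)
  brands <- unique(c(design$base_brand, ad_brand))
  comp <- lapply(brands, function(b) {
    key <- brand_component(b)
    if (!key %in% names(library$components))
      stop("design references component '", key, "' missing from the library")
    component_spectrum(library, key, grid, brand_seed = brand_seed(seed, b))
  })
  names(comp) <- brands

  spectra <- with_seed(seed, {
    lapply(seq_len(nrow(design)), function(i) {
      base <- comp[[design$base_brand[i]]]
      adul <- comp[[ad_brand[i]]]
      s <- mix_spectra(base, adul, design$level[i],
                       sample_id = design$sample_id[i])
      a <- s$absorbance
      if (baseline_slope > 0) {
        sl <- stats::runif(1, -baseline_slope, baseline_slope)
        a <- a + sl * (grid - mean(grid))
      }
      if (noise_sd > 0)
        a <- a + stats::rnorm(length(grid), sd = noise_sd)
      spectrum(design$sample_id[i], grid, a)
    })
  })
  names(spectra) <- design$sample_id
  structure(list(spectra = spectra, reference = design,
                 seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d spectra (%d spiked), %d points, seed %d\n",
              length(x$spectra), sum(x$reference$spiked),
              length(x$spectra[[1]]$wavenumbers), x$seed))
  invisible(x)
}
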