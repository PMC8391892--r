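test_that("band profiles peak at the center and respect the FWHM definition", {
  g <- seq(1700, 1600, by = -1)
  for (shape in c("gaussian", "lorentzian")) {
    v <- band_profile(1669, 1, 20, shape, g)
    expect_equal(v[g == 1669], 1)
    expect_equal(v[g == 1659], 0.5, tolerance = 1e-12) # c - w/2
    expect_equal(v[g == 1679], 0.5, tolerance = 1e-12) # c + w/2
  }
  expect_error(band_profile(1669, -1, 20, "gaussian", g), "amplitude")
  expect_error(band_profile(1669, 1, 0, "gaussian", g), "fwhm")
  expect_error(band_profile(500, 1, 20, "gaussian", g), "range")
})

test_that("the rose-oil component peaks at its characteristic band positions", {
  g <- default_grid()
  s <- component_spectrum(default_component_library(), "REO", g)
  a <- s$absorbance
  is_local_max <- function(wn) {
    i <- which(g == wn)
    a[i] >= a[i - 1] && a[i] >= a[i + 1]
  }
  for (wn in c(2922, 2958, 1452, 1056, 1234))
    expect_true(is_local_max(wn + (wn %% 2)), # nearest even grid point
                label = paste("local max near", wn))
  expect_error(component_spectrum(default_component_library(), "XXX", g),
               "unknown component")
})

test_that("brand jitter is deterministic in the seed and vanishes at cv 0", {
  g <- default_grid(2000, 1000, 2)
  lib0 <- default_component_library(brand_jitter_cv = 0)
  expect_equal(component_spectrum(lib0, "GEO", g, brand_seed = 1)$absorbance,
               component_spectrum(lib0, "GEO", g, brand_seed = 99)$absorbance)
  lib <- default_component_library()
  s1 <- component_spectrum(lib, "GEO", g, brand_seed = 42)
  s2 <- component_spectrum(lib, "GEO", g, brand_seed = 42)
  s3 <- component_spectrum(lib, "GEO", g, brand_seed = 43)
  expect_identical(s1$absorbance, s2$absorbance)
  expect_false(identical(s1$absorbance, s3$absorbance))
})

test_that("component library survives a YAML round trip", {
  tmp <- withr::local_tempfile(fileext = ".yml")
  lib <- default_component_library()
  write_component_library(lib, tmp)
  back <- read_component_library(tmp)
  expect_equal(back$brand_jitter_cv, lib$brand_jitter_cv)
  expect_equal(names(back$components), names(lib$components))
  for (nm in names(lib$components))
    expect_equal(back$components[[nm]]$amplitude,
                 lib$components[[nm]]$amplitude)
})

test_that("volumetric mixing is exact at the endpoints and affine between", {
  g <- default_grid(1800, 1600, 2)
  set.seed(2)
  base <- spectrum("REO", g, runif(length(g)))
  adul <- spectrum("PEO", g, runif(length(g)))
  expect_equal(mix_spectra(base, adul, 0)$absorbance, base$absorbance)
  expect_equal(mix_spectra(base, adul, 100)$absorbance, adul$absorbance)
  m50 <- mix_spectra(base, adul, 50)
  expect_equal(m50$absorbance, (base$absorbance + adul$absorbance) / 2)
  # affine in any window: mixture mean equals mix of component means
  for (l in c(2, 16, 64)) {
    m <- extract_windows(mix_spectra(base, adul, l), wn_window(1750, 1650))
    bw <- extract_windows(base, wn_window(1750, 1650))
    aw <- extract_windows(adul, wn_window(1750, 1650))
    expect_equal(mean(m$absorbance),
                 (1 - l / 100) * mean(bw$absorbance) +
                   l / 100 * mean(aw$absorbance), tolerance = 1e-12)
  }
  expect_error(mix_spectra(base, adul, 101), "level")
  expect_error(mix_spectra(base, spectrum("x", g + 1, g), 10), "grid")
})

test_that("the spiked design enumerates 7 pairings x 8 levels with 42 spiked rows", {
  d <- generate_design()
  expect_equal(nrow(d), 56)               # exhaustive enumeration: 7 x 8
  expect_equal(sum(d$spiked), 42)
  expect_equal(sum(!d$level %in% c(0, 100)), 42)
  expect_equal(length(unique(d$series)), 7)
  for (s in unique(d$series)) {
    lv <- d$level[d$series == s]
    expect_equal(sort(lv), c(0, 2, 4, 8, 16, 32, 64, 100))
  }
  expect_true(all((d$adulterant == "none") == (d$level == 0)))
  expect_identical(d, generate_design()) # idempotent, order-stable
})

test_that("generated datasets are seed-deterministic with calibrated noise", {
  lib <- default_component_library()
  des <- generate_design()
  g <- default_grid(2200, 1600, 2) # reduced grid keeps this quick
  clean <- generate_dataset(lib, des, grid = g, noise_sd = 0, seed = 5)
  # noise-free limit reproduces the mixing formula exactly
  i <- which(des$series == "GEO2 REO2" & des$level == 32)
  expect_equal(length(clean$spectra), nrow(des))
  jb <- clean$spectra[[which(des$series == "GEO2 REO2" & des$level == 0)]]
  ja <- clean$spectra[[which(des$series == "GEO2 REO2" & des$level == 100)]]
  expect_equal(clean$spectra[[i]]$absorbance,
               0.68 * jb$absorbance + 0.32 * ja$absorbance,
               tolerance = 1e-12)
  # determinism
  d1 <- generate_dataset(lib, des, grid = g, noise_sd = 0.003, seed = 9)
  d2 <- generate_dataset(lib, des, grid = g, noise_sd = 0.003, seed = 9)
  expect_identical(lapply(d1$spectra, `[[`, "absorbance"),
                   lapply(d2$spectra, `[[`, "absorbance"))
  # residual sd against the noiseless dataset ~ noise_sd within 10%
  res <- unlist(Map(function(a, b) a$absorbance - b$absorbance,
                    d1$spectra, clean$spectra))
  expect_equal(sd(res), 0.003, tolerance = 0.1)
  bad <- des; bad$series[1] <- "ZZZ1 REO1"
  expect_error(generate_dataset(lib, bad, grid = g), "missing from the library")
})

test_that("window-integrated absorbance rises with level for each adulterant", {
  lib <- default_component_library()
  g <- default_grid()
  wins <- list(PEO = wn_window(1700, 1600), GEO = wn_window(1218, 1130),
               PEOH = wn_window(710, 690))
  reo <- component_spectrum(lib, "REO", g)
  for (ad in names(wins)) {
    ads <- component_spectrum(lib, ad, g)
    tot <- vapply(c(0, 2, 4, 8, 16, 32, 64, 100), function(l)
      sum(extract_windows(mix_spectra(reo, ads, l), wins[[ad]])$absorbance),
      numeric(1))
    expect_true(all(diff(tot) > 0), label = paste(ad, "window contrast"))
  }
})
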