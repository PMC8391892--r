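Package: rosaftir
Title: FTIR Chemometrics for Quantifying Adulterants in Rose Essential Oil
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying common adulterants (palmarosa oil, geranium
    oil, phenylethyl alcohol) in Rosa damascena essential oil from mid-infrared
    attenuated total reflectance (ATR-FTIR) absorbance spectra. Provides
    partial least squares regression (PLSR) and principal component regression
    (PCR) calibration with leave-one-out cross-validation (PRESS, SECV, bias,
    R-squared, calibration line), Savitzky-Golay derivative and vector
    normalization preprocessing, Ward/Euclidean hierarchical clustering and
    principal component analysis of spectra, and a synthetic spectrum
    generator that emulates the spiked-sample design so the full workflow can
    be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    signal,
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
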