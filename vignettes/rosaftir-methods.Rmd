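---
title: "Models and methods behind rosaftir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rosaftir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosaftir)
```

`rosaftir` quantifies three common adulterants of Damask-rose essential oil
— palmarosa oil (PEO), geranium oil (GEO) and phenylethyl alcohol (PEOH) —
from mid-infrared ATR absorbance spectra, and classifies authentic versus
spiked samples. This vignette documents the statistical models, the
synthetic-data generator, and every numerical convention the package
commits to, so results are interpretable and reproducible.

## Calibration models

Both calibration methods are inverse, single-response models fitted on
mean-centred data; spectra are never variance-scaled, since all channels
share the same absorbance units.

**PLSR (PLS1).** For a calibration matrix $X$ ($n$ samples $\times$ $p$
points) and concentrations $y$ (% v/v), each latent factor is extracted
with the NIPALS recursion. For a single response the weight vector is
closed-form — $w \propto X^\top y$ on the deflated data, normalised to unit
length — so no iteration or convergence tolerance is involved. Scores are
$t = Xw$, X-loadings $p = X^\top t / t^\top t$, and both $X$ and $y$ are
deflated before the next factor. Coefficients are assembled as
$B = W (P^\top W)^{-1} q$.

**PCR.** The centred $X$ is decomposed by SVD; $y$ is regressed on the
first $k$ score vectors, ordered by decreasing singular value. Each
loading's sign is fixed so that its largest-magnitude element is positive,
making results platform-stable; the same convention is used by
`pca_decompose()`. Requesting more components than the numerical rank of
the centred matrix is an error.

At $k = \min(n-1, p)$ with full-rank $X$ both methods coincide with
ordinary least squares; the test suite verifies this to $10^{-8}$ against
a normal-equations solve, and verifies the PLSR predictions against an
independent established PLS implementation on random instances.

**Factor count.** The default is $k = 3$, the conventional choice for a
single-analyte window. `select_factors()` instead picks the $k$ with
minimal leave-one-out PRESS, breaking ties toward the smaller (more
parsimonious) model. `run_calibration()` additionally caps $k$ at the
numerical rank of the centred calibration matrix: noise-free synthetic
mixtures of two components have centred rank 1, and silently fitting
ill-defined factors would be misleading.

## Cross-validation metrics

Validation is leave-one-out: each sample is predicted by a model refitted
(including re-centring) on the other $n-1$ samples. The metric
conventions are:

* **PRESS** $= \sum_i (\hat y_i - y_i)^2$, in (% v/v)².
* **SECV** $= \sqrt{\mathrm{PRESS}/n}$ with $n$ the calibration-set size
  (8 per series here). This convention — rather than $n-1$ or a
  degrees-of-freedom correction — is adopted because it exactly reproduces
  the printed PRESS/SECV pairs of the published palmarosa and geranium
  calibration tables this workflow mirrors.
* **Bias** is the absolute value of the mean residual. Reporting the
  magnitude matches chemometric practice where bias tables are
  sign-free.
* **R²** is the squared Pearson correlation of actual and cross-validated
  predicted concentrations. Computing it on cross-validated rather than
  in-sample predictions is the stricter choice and matches
  cross-validation scatter plots.
* The **calibration line** regresses predicted on actual,
  $\hat y = a\,y + b$; slopes slightly below 1 with small positive
  intercepts are the expected attenuation signature of cross-validated
  predictions.

Predictions are deliberately not clipped to $[0, 100]$ % v/v, so that
metric values faithfully reflect model error.

## Preprocessing

**Derivatives** use Savitzky–Golay local polynomial fits, the de-facto
standard for instrument software. Defaults: window 9 points, polynomial
order 3, applied along the physical wavenumber axis — the signed grid step
enters the weights, so a descending grid yields d/dν, not an index-based
difference. The grid must be uniform (checked to $10^{-6}$ relative). At
the `(window-1)/2` points nearest each end the polynomial is refitted on
the truncated one-sided window rather than extrapolated. Analytic checks
(second derivative of a quadratic, annihilation of linear baselines) are
held to $10^{-6}$–$10^{-8}$ at interior points.

**Vector normalization** subtracts the spectrum mean and scales to unit
Euclidean norm, the convention of common FTIR instrument software; the
output is dimensionless, idempotent under re-normalization and invariant
to input scaling. Constant spectra raise an error rather than returning
NaN.

**Order of operations** in `apply_pipeline()`: derivative on the full
grid first, then window extraction, then normalization over the
concatenated windowed points. Differentiating before windowing keeps SG
edge effects outside the analysis windows; normalizing after windowing
normalizes over the selected frequency ranges only. The alternative order
differs near window edges, and the pipeline's contract is pinned by a
dedicated test.

## Clustering and PCA

Hierarchical clustering uses Ward's minimum-variance criterion on plain
Euclidean distances with merge heights on the Euclidean scale (the
`ward.D2` convention), under which two singletons merge at exactly their
Euclidean distance. The implementation is validated against a brute-force
agglomerator that recomputes the within-cluster variance increase from
scratch at every step. Tie-breaking under exactly equal merge costs
follows the underlying `hclust` machinery; on continuous spectral data
exact ties do not occur. Cluster labels from `cut_dendrogram()` are
deterministic (cluster 1 contains the lowest sample index). Dendrograms
export to ultrametric Newick with leaf branches equal to the absorbing
merge height, so all root-to-leaf path lengths are equal.

## The synthetic-data generator

No instrument data are distributed with this workflow, so the generator is
a first-class, tested component that emulates the study conditions:

* **Design.** Seven oil/adulterant pairings (PEO1–3 and GEO1–3 against
  REO1–3, PEOH against REO1), each at spiking levels 0, 2, 4, 8, 16, 32,
  64 and 100 % v/v — 56 samples of which 42 are spiked.
* **Spectra.** Each pure component is a sum of Gaussian bands. The
  rose-oil model carries the 13 characteristic band positions of the oil
  (3345–829 cm⁻¹); only the *positions* are anchored to published band
  tables. Amplitudes (0.1–0.6 AU, C–H stretches and the 1005/1056 cm⁻¹
  fingerprint bands strongest) and widths (10–40 cm⁻¹) are plausible
  values for neat-oil ATR spectra chosen by us.
* **Mixing** is volumetric Beer–Lambert:
  $A = (1 - \ell/100) A_\text{base} + (\ell/100) A_\text{adulterant}$.
* **Brand jitter.** Each named brand multiplies every band amplitude by an
  independent lognormal factor (mean 1, CV 0.05 by default), seeded from
  the brand name, emulating the slight intensity differences between
  commercial brands.
* **Noise and baseline.** I.i.d. Gaussian noise (default sd 0.003 AU per
  point) plus an optional random linear baseline per sample. `noise_sd`
  is the noise of the *delivered* spectrum; an instrument averaging three
  scans with single-scan noise $\sigma$ delivers $\sigma/\sqrt{3}$, and
  users should fold such averaging into the value they pass.
* **Grid.** 4000→600 cm⁻¹ descending in 2 cm⁻¹ steps (1701 points), a
  plausible digitization for a 4 cm⁻¹-resolution instrument; the actual
  point spacing of the reference instrument is not documented, so this is
  a configurable default, not a claim.

**Adulterant band choices.** The adulterants' numerical band parameters
are simulation scaffolding, not claims about PEO/GEO/PEOH chemistry. They
are constrained by the workflow's documented qualitative behaviour:
each adulterant has a marker band with strong positive contrast inside its
quantification window (PEO 1672, GEO 1170, PEOH 700 cm⁻¹), so
window-integrated absorbance rises strictly with spiking level; and the
terpene oils (PEO, GEO) are spectrally close to rose oil — they share
major constituents — while PEOH, an aromatic alcohol of a different
compound class, is given intense, narrow monosubstituted-benzene bands
(3029, 1604, 1496, 746, 700 cm⁻¹). The PEOH intensities were set so that
its second-derivative norm over the clustering windows is roughly five
times the rose oil's: a Ward merge-cost analysis shows this places the
2-cluster boundary of the dendrogram between the 8 % and 16 % PEOH levels,
reproducing the reported structure in which PEOH and its higher spiking
levels occupy their own dendrogram arm.

**What the generator does not emulate:** ATR penetration-depth and
refractive-index dispersion, scattering artifacts, water-vapour and CO₂
lines, band-shape asymmetry, and nonlinear detector response. Passing
tests on this generator therefore demonstrate that the chemometric
machinery is correct and achieves the published quality regime on data
with the stated design and noise structure — not that the specific
published concentrations would be recovered from real oils.

## Validation problem sizes

The packaged checks run the full 42-model grid (7 series × 2 methods × 3
preprocessing variants) on 20 simulated datasets per noise level
(0.003 and 0.002 AU), and the clustering property on 50 simulated
datasets; brute-force oracles (naive Ward, per-fold OLS, covariance
eigensolves) are run at $n \le 8$. These sizes keep the suite fast while
exercising every code path at the study's own scale ($n = 8$ per
calibration series).

## Known limitations

* PLS2 (multiple simultaneous responses), test-set validation,
  uncertainty intervals and spectral-residual outlier tests are out of
  scope.
* Calibration assumes the mixture's absorbance is affine in volume
  fraction; strongly interacting mixtures violating Beer–Lambert
  additivity are not modelled.
* The JCAMP-DX reader supports only the uncompressed
  `##XYDATA=(X++(Y..Y))` tabular form with AFFN numerals.
* Proprietary binary instrument formats (OPUS, GRAMS `.spc`) are not
  read; the interchange format is a wide CSV (`wavenumber` column plus
  one column per sample).
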