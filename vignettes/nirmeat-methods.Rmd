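---
title: "Methods: Vis/NIR calibration of meat quality with nirmeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Vis/NIR calibration of meat quality with nirmeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirmeat)
```

## Scope and model

`nirmeat` builds and evaluates Vis/NIR reflectance calibrations for six meat
physicochemical properties: pH, CIELAB L\*/a\*/b\*, cooking loss (%) and
shear force (N). The statistical engine is univariate partial least squares
regression (PLS1, NIPALS algorithm) on mean-centered spectra, with the
latent-variable count chosen by leave-one-out cross-validation and model
quality summarized by R², RMSE and the residual predictive deviation
RPD = SD(prediction-set references)/RMSEP. This vignette records the
modelling assumptions, the tunable parameters that matter, what the
synthetic data generator does and does not emulate, and the design choices
made where more than one defensible option existed.

## The synthetic world

No spectra ship with the package; `generate_dataset()` produces them. Its
defaults *are* the stated experimental world: a 5-day x 5-carcass x 6-cut
design (150 samples), a 400-1000 nm grid at 0.6 nm, five replicate scans
per sample, and per-cut property distributions with the documented means,
SDs and min/max bounds (`default_property_distributions()`).

**Properties.** Per cut, property vectors are drawn from a multivariate
normal truncated to the per-cut [min, max] box (rejection sampling, capped
at 1000 attempts per sample). All cuts share one within-cut correlation
matrix. Because the configured correlation target refers to properties
*pooled across cuts*, and because both the between-cut spread of means and
the box truncation distort pooled correlations, the within-cut matrix is
*calibrated*: the generator solves the pooled-covariance decomposition for
the within-cut part and then refines it with a short Monte-Carlo fixed
point (fixed internal seed, so the calibration is deterministic and
independent of the user's seed). The residual error of the realized pooled
correlation is about 0.01 asymptotically; at n = 6000 the empirical matrix
sits within about 0.03 of the target, and the test suite asserts 0.05.

**Spectra.** Absorbance is Beer-Lambert-like:
$A(\lambda) = \sum_k c_k \exp(-(\lambda-\mu_k)^2/2\sigma_k^2) + A_0(\lambda)
+ \tau\,(\lambda - \lambda_{mid})$, with clean reflectance $10^{-A}$. Four
sharp default bands sit at 430, 550, 760 and 980 nm — the haem/Soret and
myoglobin features in the visible range and the O-H overtone bands in the
NIR that make meat spectra informative. Two broad auxiliary bands (650 and
880 nm, widths 65/70 nm) are added so that the fixed linear map from the
six standardized properties to band concentrations is square and
well-conditioned. This is deliberate: with only four latent channels a
six-dimensional, nearly full-rank property vector is not linearly
recoverable from noiseless spectra, so the package's own
parameter-recovery guarantee (R²p >= 0.95 in the noiseless limit) would be
unattainable by construction. The linear property-to-concentration link
(`band_amplitude`, default 0.06 absorbance units per pooled SD) keeps the
world inside PLSR's linearity assumptions up to the mild curvature of the
$10^{-A}$ transform.

**Acquisition.** Each replicate scan is contaminated with a multiplicative
factor $(1+\alpha)$, an additive offset $\beta$ and white noise, then the
replicates are averaged — the replicate-averaged acquisition protocol of
portable fibre-probe instruments. Defaults: `scatter_multiplicative_sd`
0.05, `scatter_additive_sd` 0.01, `baseline_tilt_sd` 2e-4 per nm,
`noise_sd` 0.002, chosen as the scale of artefact a handheld reflectance
probe with a 300:1 SNR and repositioned replicate scans plausibly shows.
These are exactly the distortions MSC, SNV and detrending are designed to
remove, which is what makes the generator a meaningful test bed for the
preprocessing comparison.

**What the generator does not emulate** — and hence what a green test does
not establish: wavelength-dependent (coloured) instrument noise, detector
nonlinearity, Kubelka-Munk radiative transfer in a scattering matrix,
temperature drift, and any cut-specific optical geometry (the tenderloin's
irregular shape is treated like every other cut; only the property
distributions differ between cuts). Passing the recovery tests shows the
pipeline is correct on a linear-in-concentration world, not that real
multi-cut spectra reach any particular accuracy.

## Preprocessing operators

All operators act row-wise on a `spectra_set` and are permutation
equivariant; only MSC carries fitted state.

- **Trimming**: closed interval, default 400-1000 nm; instrument extremes
  are noise-dominated.
- **SNV** standardizes each spectrum to mean 0, SD 1, using the n-1
  denominator (documented; the population variant would only rescale all
  rows by one common factor).
- **MSC** regresses each spectrum on a reference by OLS and returns
  $(x-a)/b$. The reference defaults to the calibration-set mean and is
  *frozen* into the chain state, so prediction spectra are corrected
  against the calibration reference — refitting MSC on the prediction set
  would leak information and silently change the model's input space.
- **Detrend** subtracts the least-squares polynomial in wavelength, default
  degree 2 (the conventional SNV-detrend pairing).
- **Savitzky-Golay** filtering uses local polynomial least squares on the
  uniform grid; derivatives are S-G derivatives (never raw finite
  differences, which amplify noise), scaled to per-nm units. Window 5 and
  polynomial order 2 are the defaults for both smoothing and derivatives —
  order 2 is the conventional chemometrics choice when only the window is
  specified. Edges are handled by evaluating the first/last full-window
  polynomial fit at the edge points, so the filter is exact on polynomials
  up to the fit order *everywhere*; reflection padding would break that.
- **Chains**: the eight standard variants ship as presets; combination
  order follows the label: smoothing, then detrend, then scatter
  correction. MSC and SNV are mutually exclusive in one chain. An optional
  `absorbance` step (log10(1/R)) is available for users who prefer scatter
  correction on the absorbance scale; the default operates on reflectance
  as acquired.

## Sample-set division

- **Concentration gradient**: sort by the reference value (ties broken by
  sample id for determinism), partition into consecutive blocks of four
  (final block possibly smaller), draw exactly one sample per block —
  including the partial block — into the prediction set. On n = 150 this
  yields 38/112, the arithmetic that motivates the partial-block rule.
  Splits are made independently per property.
- **Whole-carcass hold-out**: all cuts of the held-out carcasses are
  predicted; the default schedule holds out 2+2+1+1+1 carcasses over five
  days (42/108 on the default design), taking the lowest carcass ids per
  day. Which carcasses to hold out is genuinely underdetermined; an
  explicit id list overrides the schedule.

A property of the gradient scheme worth knowing: the prediction range
escapes the calibration range exactly when a boundary block's extreme
sample is the one drawn. For n = 150 (final block of 2) that happens with
probability 1 - (3/4)(1/2) = 5/8, so range coverage in any single draw is
the *minority* outcome — the test suite asserts this closed form rather
than a folk expectation that coverage "usually" holds.

## PLSR and latent-variable selection

NIPALS for a univariate response needs no inner iteration; each component
is a closed-form step followed by deflation. Components stop early with a
warning if the residual covariance vanishes (exact fit). The composite
coefficient vector uses the triangular structure of $P^\top W$. Spectra
are mean-centered only by default — autoscaling (`scale = TRUE`) is
available but rarely appropriate for spectra, where the wavelength-wise
variance structure is informative.

LOOCV refits the model on every leave-one-out fold; each fold is fitted
once to the maximum order and its whole coefficient path evaluated, which
is algebraically identical to the brute-force per-k refit loop (asserted
against exactly that loop in the tests) at a fraction of the cost. The
chosen count minimizes RMSECV with ties broken toward fewer components;
`max_components` defaults to 15. The reference implementation used to
cross-check coefficients is an independently coded SIMPLS, which is exact
for PLS1.

## Evaluation conventions

- **R²** is 1 - SSE/SST about the observed mean; the squared-Pearson
  variant is available behind a flag. The two differ for biased
  predictions, and the difference is visible in held-out statistics.
- **RMSE** uses the n divisor; **RPD**'s SD uses n-1. This combination
  reproduces standard published RPD values from their printed SD/RMSEP
  pairs at two-decimal rounding, which is how the consistency tests pin it.
- Reports round to 2 decimals for display; stored values are full
  precision. Best-per-property selection maximizes RPD with ties broken
  toward fewer latent variables.

## Numerical choices and degenerate inputs

Constant spectra are rejected by SNV (zero spread) and MSC rejects
spectra uncorrelated with the reference (|b| < 1e-12). Detrend and the S-G
edge fits use scaled bases/QR for conditioning. The truncation sampler
reports the cut and the tightest-bound property when its retry cap is hit.
A non-positive-definite correlation target is rejected at configuration
time with the offending minimum eigenvalue. All randomness flows from one
integer seed per entry point through an RNG-state-preserving wrapper, so
package calls never disturb the caller's RNG stream; grid runs are
byte-reproducible given (config, seed).

## Test-time scaling

The full-resolution default grid (0.6 nm, 1001 points) is exercised by the
generator tests, but the model-fitting acceptance tests run on a 3 nm grid
(201 points) to keep the suite inside its time budget. The band structure
(narrowest band SD 22 nm) is fully resolved at 3 nm, so this changes
compute, not conclusions.

## Known limitations

Univariate PLS only (one model per property; no PLS2), no outlier
diagnostics (leverage/Q residuals), no wavelength-interval selection, no
Kennard-Stone/SPXY splitting, and no claim that synthetic-world accuracies
transfer to instrument data. The generator's property distributions and
correlation targets are fixed transcriptions of a single multi-cut sheep
study design; other species, cut sets or instruments need their own
configuration.
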