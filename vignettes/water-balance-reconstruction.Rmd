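---
title: "Pollen-based water-balance reconstruction: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pollen-based water-balance reconstruction: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleowb)
```

`paleowb` implements a complete proxy–model comparison pipeline for Holocene
hydroclimate: pollen–climate transfer functions, regional bootstrap synthesis,
trend and mode decomposition, periodicity analysis, and coupling analysis
between atmospheric-circulation and moisture fields. This vignette is the
package's account of the science behind each stage: the models and their
assumptions, the parameters that matter, the numerical choices, and the
limits of what the synthetic-data tests demonstrate.

## Transfer functions

### Modern analog technique

MAT assumes that compositionally similar pollen spectra come from similar
climates. For a fossil spectrum, the k closest calibration spectra under the
squared-chord distance

$$d(p, q) = \sum_i\left(\sqrt{p_i} - \sqrt{q_i}\right)^2 \in [0, 2]$$

are found, and the reconstruction is their climate average weighted by
inverse distance. Defaults and conventions:

* `k = 5` analogs — the standard choice for North American pollen data.
* Weights are $1/d$ on the squared-chord distance itself. The analog
  literature uses both $1/d$ and $1/d^2$; we fixed $1/d$ as the package
  convention. An exact match ($d = 0$) takes full weight; several exact
  matches average arithmetically.
* Ties at the k-th distance resolve by stable training order, so
  reconstructions are deterministic.
* The minimum distance per fossil sample is retained; `analog_quality()`
  flags samples above 0.25, the conventional no-analog threshold.

### Boosted regression trees

BRT is a stochastic gradient-boosted ensemble of shallow regression trees.
Its appeal for moisture reconstruction is that boosting screens the
calibration data for indicator taxa with strong partial responses — useful
because pollen responds to temperature first and moisture second, and tree
ensembles can isolate the secondary signal. Settings (all tunable in
`brt_fit()`):

* learning rate 0.025, tree complexity (depth) 4, bagging fraction 0.5,
  at most 3000 trees — the standard calibration settings for this problem.
* The tree count actually used is selected by internal cross-validated
  squared-error deviance with early stopping. We use 5 folds by default:
  with a 50-round early-stopping patience the selected ensemble size is
  insensitive to the fold count, and 5 folds keep refits cheap inside
  cross-validation loops.
* The backend is xgboost with one thread and a fixed RNG seed, making fits
  bit-reproducible.

`predictor_importance()` reports per-taxon relative contributions (summing
to 100%) from per-split gain. On the default synthetic taxonomy the
water-balance model concentrates importance on the dry-prairie forbs, and
the temperature model on the warm-indicator tree — mirroring the ecological
structure such models show on real eastern North American data.

### h-block cross-validation

Spatial autocorrelation makes plain leave-one-out optimistic: the nearest
calibration sites are near-duplicates of the test site. `hblock_crossvalidate()`
excludes every site within a great-circle radius `h_km` of the test site
(haversine distance), refits, and predicts the held-out site; `h_km = 0` is
ordinary leave-one-out. The default radius is 100 km and should be chosen to
exceed the range of spatial dependence in the calibration climate. For BRT
folds the ensemble size is selected once on the full data and reused, which
keeps the n-fold refit affordable without changing the selected model class.

## Bioclimatic indices

Water balance is defined as annual precipitation minus potential
evapotranspiration, with PET tied to biotemperature:

* `mabt()`: mean annual biotemperature, $\sum_m \max(t_m, 0) / 12$. The
  truncated-mean convention ("divide by 12", the Holdridge biotemperature)
  was chosen over "mean of positive months only"; the two differ only where
  part of the year is below freezing, and the truncated mean is the one
  consistent with a PET that vanishes in fully frozen climates.
* `pet_annual()`: PET = 58.93 × MABT (mm/a), a fixed linear coefficient.
* `gdd5()`: growing degree days above 5 °C from a single-harmonic sine
  regression fitted to the 12 monthly means at the mid-days of a non-leap
  calendar (year length 365.25 d), evaluated on a daily grid. A single
  harmonic is deliberately smooth; it cannot represent asymmetric seasonal
  cycles, which is the accepted cost of this classical interpolation.

## Regional synthesis

Fossil sequences enter the synthesis only if they pass `filter_sites()`:
at least 30 samples and 5 absolute datings (125 and 9 for the
high-resolution subset), a bottom age of at least 10 ka, and a modern water
balance inside the calibration range (−348 to 1343 mm/a) by a 150 mm margin
so that past deviations in either direction remain reconstructable.

Each accepted reconstruction is expressed as the deviation from the site's
own 0–4 ka mean — aligning sites with different modern climates — and
linearly interpolated to a 50-yr grid strictly inside the record span (no
extrapolation; linearity is the least-structured choice for irregular
60–75 yr sampling). The regional curve is the mean over sites covering each
step, with the per-step site count recorded; 95% bands are the 2.5th/97.5th
percentiles of 1000 bootstrap resamples of whole sequences (sites, not
samples, are the exchangeable unit — sample-level resampling would destroy
serial structure). A five-point running mean is attached; its edge windows
shrink rather than truncate, so the smoothed curve spans the full grid.

Two caveats the package makes explicit rather than hiding:

* The bootstrap quantifies *between-site* uncertainty. Errors shared by all
  sites — in particular the attenuation ("regression to the mean") common to
  analog and regression transfer functions — are invisible to it, so bands
  understate total uncertainty when site records are near-copies of one
  regional signal. The synthetic tests therefore give sites realistic local
  climate variability around the regional trajectory; with homogeneous
  site clones the bands demonstrably undercover.
* Percentile bootstrap bands are mildly anti-conservative for few sites;
  with fewer than ~15 sequences the nominal 95% is optimistic.

`centennial_residuals()` isolates sub-millennial variability as the residual
from a locally weighted linear trend with tricube weights and a fixed 2-ka
window width. The bandwidth is fixed in time units, not as a fraction of the
series length, so records of different lengths are smoothed identically.
`rebaseline()` shifts a series to a reference window, by default the
preindustrial 0.25–0.75 ka.

## Trends and modes

### SiZer maps

`sizer_map()` classifies the smoothed derivative at every (time, bandwidth)
cell: a Gaussian-kernel local linear fit estimates the slope, and the cell
is *rising*/*falling* when the pointwise confidence interval excludes zero,
*flat* otherwise, and *insufficient* when the kernel's effective sample size
$(\sum w)^2 / \sum w^2$ is below 5. Numerical choices that matter:

* Slope variance uses the kernel-weighted sandwich estimator inflated by
  `ess/(ess − 2)` with a Student-t quantile at `ess − 2` degrees of freedom.
  Without these small-sample corrections the per-cell false-positive rate on
  white noise runs several points above the nominal 5%; with them it is
  calibrated (checked by Monte Carlo in the test suite).
* Slopes below numerical noise (relative to the series scale) are classified
  flat, so an exactly constant series can never appear significant.
* The default bandwidth grid is 16 log-spaced values spanning
  decadal-to-millennial scales of the record (0.1–4 ka for the standard
  50-yr synthesis grid).

### Principal components of the reconstruction matrix

`pca_reconstructions()` decomposes the time × site anomaly matrix over a
common window (0.25–11 ka by default; sites not covering it are dropped).
The PCA is column-centred on the covariance matrix — all columns share mm/a
units, so correlation scaling would discard genuine amplitude differences
between sites. Components are oriented for display stability: the mean site
loading of each component is non-negative, except that when longitudes are
supplied the second component is oriented so the east-minus-west loading
contrast is negative, matching the convention of plotting the east–west
moisture contrast mode with positive mid-continental loadings.

## Periodicities

`preprocess_series()` optionally degrades annual model output with a 50-yr
running mean (to match the reconstruction resolution) and removes
millennial-scale variability with a 4th-order Butterworth high-pass
(cutoff 1000 yr), run forward–backward for zero phase; order 4 gives a
steep but stable rolloff, and the input is demeaned first so the recursion
has no DC transient. `morlet_wavelet()` implements the continuous Morlet
transform (ω₀ = 6, the standard trade-off between time and frequency
localization) with scale resolution dj = 0.05 octaves (fine enough that a
±10% period match cannot fall between scales), zero padding to the next
power of two, and pointwise χ² significance against a theoretical AR(1)
spectrum whose lag-1 coefficient is estimated from the series. The cone of
influence marks the e-folding distance √2·s from each edge; cells outside
it are never significant.

`extract_significant_periods()` averages in-cone power per scale, compares
it with the correspondingly averaged 5% red-noise level, and reports local
maxima of the ratio above one as discrete periodicities. Averaging over time
(rather than counting pointwise patches) reflects the intended use:
summarizing which periods are persistently energetic in a record.
`periodicity_kde()` fits a Gaussian kernel density on the linear period axis
with Silverman's bandwidth computed from the *distinct* periods — so
duplicated detections do not sharpen the density — normalized per group.

## Field coupling

`extract_region()` takes cosine-latitude-weighted box means, with the three
default boxes (MW 42–51°N/92–100°W, GL 40–47°N/85–90°W, NE 40–47°N/69–75°W,
the last excluding ocean cells) matching the pollen site clusters.
`bin_series()` reduces annual series to 50-yr bin means with ±2σ/√n bands.
`slp_offset_correction()` subtracts the scalar global-mean SLP difference
against a reference state, removing non-dynamical offsets (sea-level and
ice-load effects) while preserving every spatial gradient exactly.

`eof_truncate()` computes area-weighted (√cos φ) EOFs of the per-cell time
anomalies and retains the leading five modes by default — enough to capture
the majority of large-scale SLP and regional moisture variance while
filtering small-scale noise before CCA. `cca()` finds maximally correlated
pairs of linear combinations of the two PC spaces, maps patterns back to
grid space by regressing each field on the standardized canonical time
coefficients, and reports per-field explained variance *without re-sorting
pairs*: the leading pair maximizes joint correlation, and its explained
variance for an individual field can legitimately be smaller than the second
pair's. Design choices left open by convention and fixed here:

* EOF PCs enter the CCA in their natural (singular-value) scaling.
* Significance is a circular moving-block permutation (block 10 yr) of one
  field's time axis, preserving autocorrelation under the null; parametric
  CCA tests assume independence that annual climate series do not have.
* Patterns are oriented so the canonical correlation is positive and the
  SLP pattern's largest-magnitude cell is positive.
* Longitudes are stored in [−180, 180]; western-hemisphere boxes are given
  as negative longitudes.

Canonical correlations estimated from noisy fields are attenuated relative
to the latent coupling between planted modes: noise leaks into the leading
PCs of both fields and dilutes their correlation. The synthetic recovery
tests therefore plant a mode that dominates the noise floor (amplitude 8
versus unit noise), as the leading modes of real large-scale SLP variability
do; with weak planted modes, recovery of the numeric coupling value is not
an achievable target for any method.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream stage is validated.

* **Calibration sets.** Site climates come from a Gaussian copula with
  uniform marginals over the calibration ranges (T_jul 8–22 °C, water
  balance −348 to 1343 mm/a) with a target Pearson correlation of −0.11 —
  the near-orthogonal gradient structure that makes independent temperature
  and moisture reconstruction possible. Expected compositions follow
  product-Gaussian (unimodal) taxon responses normalized across taxa — the
  simplest response model consistent with niche theory — and observed
  compositions are multinomial draws of the pollen count (default 400
  grains). The default eight-taxon flora includes narrow-tolerance moisture
  indicators (sagebrush-like, amaranth-like), a narrow-tolerance summer
  temperature indicator (oak-like), and broader-tolerance trees and
  graminoids, so importance analyses have a known right answer.
* **Fossil sequences.** Sample ages are irregular, with gaps uniform around
  a mean spacing (63.2 yr by default, the typical resolution of well-dated
  sequences); assemblages pass through the same response model as the
  calibration data. Sites can receive persistent local AR(1) climate
  deviations around the regional trajectory (`local_wb_sd`, default off) —
  real sequences record local hydrology, and this between-site variance is
  what the synthesis bootstrap measures.
* **Red-noise series** are stationary AR(1) processes with unit variance and
  optional injected sinusoids, the standard fixture for significance
  calibration.
* **Coupled fields** plant shared time coefficients (correlation
  `coupling_r`) on chosen SLP/moisture spatial patterns, plus spatially
  smoothed noise.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: chronological (age-model) uncertainty, overdispersion
beyond multinomial counting noise, taxonomic harmonization error, human
impact on surface samples, and secular changes in taxon–climate
relationships. Ages are taken as given everywhere (cal ka BP, increasing
into the past).

## Problem sizes

The test suite validates the end-to-end recovery at a calibration size of
2419 samples and 20 sequences per region — the scale of the real eastern
North American datasets — and uses smaller sizes (a few hundred calibration
samples, 3–10 sequences) for unit and pipeline tests. Monte-Carlo
calibration checks use 25–100 replicate series of 160–200 points. The
bootstrap default is 1000 replicates; permutation tests default to 999 and
use 99–199 in tests.

## Known limitations

* Transfer-function attenuation biases both MAT and BRT toward the
  calibration mean; regional amplitude estimates are conservative, and
  bootstrap bands do not include this shared bias (see above).
* The AR(1) red-noise background is estimated from the analyzed series
  itself; strongly periodic series inflate the estimated background and make
  the significance test conservative.
* `gdd5()`'s single-harmonic interpolation underestimates degree days in
  climates with strongly skewed seasonal cycles.
* CCA patterns are regression (homogeneous) maps; heterogeneous maps and
  cross-validated pattern skill are out of scope.
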