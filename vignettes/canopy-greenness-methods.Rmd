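---
title: "From canopy photographs to phenophase transition dates: methods"
author: "canopygcc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From canopy photographs to phenophase transition dates: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 3.5)
library(canopygcc)
```

`canopygcc` turns directories of time-lapse RGB canopy photographs into
quality-controlled greenness time series and phenophase transition dates
with uncertainties. This vignette explains the models and procedures the
package implements, the parameters that matter and their defaults, the
numerical decisions taken where the design was genuinely open, and what
the synthetic-site generator does and does not emulate.

## The greenness index

Each 24-bit JPEG stores a digital number (DN, 0–255) triplet per pixel.
Raw channel intensities are dominated by weather, solar geometry and
in-camera exposure control, so the pipeline works with chromatic
coordinates computed from the ROI-mean DN of each channel:

$$G_{cc} = \frac{G_{DN}}{R_{DN} + G_{DN} + B_{DN}}, \qquad
  R_{cc} = \frac{R_{DN}}{R_{DN} + G_{DN} + B_{DN}}.$$

Dividing by total brightness cancels multiplicative exposure changes
exactly, which is why $G_{cc}$ tracks the seasonal trajectory of canopy
colour through highly variable illumination. Achromatic scenes — snow,
fog, leafless grey branches — sit near $G_{cc} = 1/3$, a fact the tests
use as a fixed point. The coordinates are computed from channel *means*
over the ROI (not per pixel and then averaged); the all-image product
also stores per-channel means, population standard deviations, seven
percentiles (5, 10, 25, 50, 75, 90, 95) and the three inter-channel
Pearson correlations, so other indices can be derived downstream.

## Per-image processing

The image timestamp is parsed from the
`<sitename>_<YYYY_MM_DD>_<hhmmss>.jpg` filename; times are local
standard time and daylight saving is never applied. Solar elevation is
computed with the NOAA low-precision ephemeris (solar declination,
equation of time, hour angle), ignoring atmospheric refraction: the
downstream filter threshold is 10°, so the ~0.1–0.3° accuracy of this
formulation is ample.

Each image is matched against the ROI mask sequence: binary 8-bit TIFF
masks (black = included) valid over date/time windows listed in the ROI
list file. Windows are treated as closed intervals at both ends, and
overlaps resolve to the first matching entry with a warning — the file
format does not state boundary semantics, so the package fixes them.
Pixels with DN < 128 count as included, so mid-grey and brighter is
excluded. When image dimensions differ from the mask (some cameras
change resolution over time), the image is resampled to the mask size by
separable bilinear interpolation; nearest-neighbour resampling would
alias thin canopy structures into the colour statistics.

## Quality control and aggregation

Images are excluded from aggregate statistics when solar elevation is
below 10°, or the ROI-mean DN sum is above 665 ("too bright") or below
100 ("too dark"). All three comparisons are strict, so boundary values
pass. Within a typical forest canopy ROI the DN sum is roughly 150–250,
comfortably inside the window.

Summaries are produced on fixed day-of-year grids so that rows align
across years: daily windows for the 1-day product, and 3-day windows
centred on doy 2, 5, …, 365 for the 3-day product. The final 3-day
window keeps the label 365 and simply holds two member days in non-leap
years (three in leap years, absorbing doy 366). Each row reports two
sets of statistics: those of the *midday image* — the image closest to
12:00:00 local standard time on the window's middle day, chosen without
QC filtering and with ties going to the earlier image — and aggregates
(mean, SD, 50th/75th/90th percentiles of $G_{cc}$ and $R_{cc}$; channel
means and SDs) across all QC-passing images in the window. Standard
deviations across fewer than two images are reported `NA` rather
than 0. Snow flags (codes 1–5 from visual classification of midday
images) are consumed from an external two-column table keyed by midday
filename; producing them is out of scope.

## Smoothing and outlier rejection

Each of the eight summary series (`gcc_mean`, `gcc_50`, `gcc_75`,
`gcc_90` and the $R_{cc}$ counterparts) is smoothed independently with a
cubic smoothing spline. The smoothing level is selected by the corrected
AIC for nonparametric regression,

$$\mathrm{AICc} = \log(\mathrm{RSS}/n) +
  \frac{1 + \mathrm{edf}/n}{1 - (\mathrm{edf} + 2)/n},$$

with the effective degrees of freedom taken as the trace of the linear
smoother matrix. Candidates are a fixed grid of 30 smoothing values
spanning near-interpolation to the linear (edf = 2) limit, log-spaced in
the spline's native smoothing parameter; a fixed grid makes selection
deterministic, and ties resolve to the smoother fit.

Residuals are modelled as Laplace (double-exponential): large greenness
excursions from snow, fog and bad exposures make the residual
distribution heavy-tailed, and the Laplace maximum-likelihood scale —
the mean absolute residual $b$, with $\sigma = \sqrt{2}\,b$ — is the
natural robust scale estimate. Outlier rejection iterates up to 20
times: fit the AICc-selected spline to the unflagged points, estimate
$\sigma$, flag points more than $4\sigma$ above or $2\sigma$ below the
spline, and stop when a pass adds no flags. The asymmetry filters
downward excursions more aggressively because they are larger and more
common than upward ones. Two details are deliberate:

* **The scale is estimated from the residuals of all points**, flagged
  ones included, about the current spline. Estimating it from survivors
  only would shrink the threshold after each pass and progressively eat
  the noise tail: for Laplace noise, about 3% of clean points lie below
  $2\sigma$, and iterating on survivor-based scales flags 4–6% of clean
  data. With the conservative scale, clean points are flagged at well
  under 1% while gross excursions (which exceed the threshold by
  construction) are still caught.
* **Flagging is not attempted below a scale floor** of
  `min_sigma = 1e-4` $G_{cc}$ units. Below that level the residuals are
  at the resolution of 8-bit quantisation and reflect spline
  approximation error rather than observation noise, so "outliers"
  would be meaningless.

After the last pass the spline is refit once more on the unflagged
points; this final fit supplies the smoothed values reported on *every*
window date (interpolating gaps), the residual RMSE (reported in the
transition-date file header; seasonal amplitude divided by this RMSE is
a useful signal-to-noise measure), and a confidence band of constant
half-width $1.96\sigma$, with $\sigma$ now estimated from the retained
residuals. Leverage-weighted bands were considered and rejected: the
transition-date confidence floor of one aggregation step dominates near
transitions, where the band matters. An interpolation flag marks rows
strictly inside gaps of 14 days or more between observed, unflagged
values.

## Stage segmentation and transition dates

The smoothed series, standardised to unit variance, is segmented with
PELT (Pruned Exact Linear Time) under a Gaussian change-in-mean cost
(within-segment residual sum of squares), penalty $\beta = 0.5$ per
changepoint on the standardised scale, and a minimum segment length of
14 days (⌈14/step⌉ samples, i.e. 5 samples for the 3-day product). The
cost function and the scale on which $\beta$ applies are package
decisions; standardising makes one penalty work across sites with very
different amplitudes. The implementation is exact — identical to the
O(n²) optimal-partitioning dynamic program, which the test suite
verifies on hundreds of random signals. One subtlety: with a minimum
segment length, the classical pruning rule can discard a candidate that
is still needed while its replacement is not yet eligible, so removal
is delayed by `minseg` samples.

Changepoint segments are classified by the sign of their net smoothed
change and consecutive same-direction segments are merged, so a year
may contain several rising/falling cycles and a stage may span calendar
years. Because a changepoint can sit short of the actual smoothed
extremum (e.g. on the shoulder of a plateau), each stage's baseline
minimum and peak maximum are searched over the stage *plus its
neighbouring stage* on the relevant side. Stages whose amplitude falls
below `max(2 × RMSE, 0.01)` are discarded as noise: the 2 × RMSE floor
suppresses micro-stages on flat (e.g. evergreen) series, and the
absolute 0.01 $G_{cc}$ floor matches the conservative 99% confidence
width of an individual $G_{cc}$ value established by reference-panel
analysis — an amplitude below it is not a resolvable vegetation cycle.

For each stage, threshold values at 10%, 25% and 50% of the amplitude
(`min_gcc + f × (max_gcc − min_gcc)`) are located on the smoothed curve
at the product's native date resolution: the first crossing date within
the stage for rising stages, the last for falling. Sub-step
interpolation is pointless because the confidence floor equals one
step. Confidence-interval dates are the corresponding crossings of the
curve shifted up and down by the $1.96\sigma$ band, expanded to at
least one step either side, and widened to the nearest observed value
when data are missing next to the transition. When a shifted curve
never crosses the threshold inside the stage, the interval endpoint is
clamped to the stage boundary with a warning.

## Calibration utilities

The sensor response of a camera is summarised by
$y = a\,e^{b x} + \varepsilon$, with $x$ the natural log of exposure and
$y$ the DN output, fitted as a linear regression of $\ln y$ on $x$.
Points above DN 220 are excluded: response curves bend away from the
exponential as channels approach saturation, and the fitting loss was
not otherwise specified. Reference-panel stability is quantified as the
sample SD of panel $G_{cc}$ after restricting to solar elevation above
5° and panel brightness in [200, 565]; 2.5 × SD is reported as a
conservative 99% interval half-width for individual $G_{cc}$ values.
For cross-camera comparison, `relative_gcc()` linearly rescales a
season so the dormant-window mean (doy > 290 or < 110) is 0 and the
peak-summer mean (doy 150–180) is 1.

## The synthetic-site generator

Synthetic sites make every stage testable without real imagery. The
seasonal trajectory is the standard double-logistic pulse

$$g(t) = \mathrm{baseline} + A\left[\mathrm{logis}(r_s(t - m_s)) -
  \mathrm{logis}(r_a(t - m_a))\right],$$

optionally summed over two pulses for bimodal sites. Defaults describe
a temperate deciduous broadleaf canopy: baseline 0.35, amplitude 0.10,
spring midpoint day 120 at rate 0.15 d⁻¹, autumn midpoint day 270 at
rate 0.10 d⁻¹ (spring green-up is faster than autumn green-down), at a
site (42.5° N, 72.2° W, UTC−5) where noon sun clears the 10° filter
year-round. Observation noise is Laplace, matching the outlier model;
the `noise` parameter is its standard deviation. Snow days pull
$G_{cc}$ to the achromatic 1/3; gross outliers depress it by about ten
noise SDs; per-image multiplicative illumination factors
$e^{N(0,\;\mathrm{illum\_sd})}$ exercise the exposure invariance; and an
optional field-of-view shift translates the scene background and opens
a second mask entry. True transition dates are solved from the
noiseless trajectory by bisection, so recovery can be scored exactly.

Rendered images are deliberately simple — a brightness-ramp "landscape"
above a uniform ROI block whose colour solves for the target
$G_{cc}$ at a DN-sum budget of 300 — and are written at JPEG quality
0.95, bounding quantisation effects at roughly 0.005 $G_{cc}$. The
generator does **not** emulate shadows and within-ROI texture,
temporally autocorrelated weather, diurnal illumination cycles, mixed
pixels at canopy edges, or camera drift. Passing tests therefore
demonstrate the correctness of the algorithms under the stated noise
model, not robustness to every artefact of field imagery; the
quality-control thresholds and the visual-inspection workflow the file
formats support exist precisely because real imagery is messier.

## Problem sizes and tolerances in the test suite

The suite verifies PELT against the exhaustive dynamic program on 100+
random signals of length ≤ 60; percentile and SD statistics against
sort-based oracles on 1000-pixel ROIs; transition recovery on 50 seeded
3-day series (amplitude 0.10, Laplace σ = 0.004), requiring median
50%-date error ≤ 3 d and truth inside the reported interval in ≥ 90% of
stages; outlier recovery on 50 seeded series with 3% gross negative
outliers at σ = 0.005, requiring ≥ 90% recovery with ≤ 2% false
positives; and a full image-to-transition-dates run on a noiseless
365-image site, requiring every true date within one sampling step and
byte-exact round-trips of all five product file dialects. These sizes
keep the whole suite under a minute on one core while leaving the
statistical checks comfortably powered.

## Known limitations

* Transition dates are reported at the product's native resolution, so
  a systematic half-step rounding (late for rising, early for falling)
  is visible on noiseless data.
* The confidence band has constant width; uncertainty is underestimated
  at series edges and inside long interpolated gaps (the interpolation
  flag marks the latter).
* Exact re-running of the iterative outlier filter on a series with its
  flagged points already removed may trim a few additional noise-tail
  points, because removing gross outliers tightens the conservative
  scale estimate; the smoothed curve moves by well under one residual
  SD.
* The solar ephemeris ignores refraction and topographic shading; near
  the 10° filter threshold in mountainous terrain this can admit images
  a purist would exclude.

## A worked example

```{r example}
spec <- synthetic_site_spec(step = 3, noise = 0.004, seed = 42,
                            outlier_frac = 0.02)
gen <- make_series(spec)
s <- summary_from_series(gen$series, step = 3)
td <- extract_transition_dates(s)
td[td$gcc_value == "gcc_50",
   c("direction", "transition_10", "transition_25", "transition_50")]
gen$truth$transitions[, c("direction", "transition_10",
                          "transition_25", "transition_50")]
```

```{r plot}
autoplot(s, statistic = "gcc_50")
```
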