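---
title: "Rule-based rice area and Start-of-Season mapping from multi-temporal SAR backscatter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based rice area and Start-of-Season mapping from multi-temporal SAR backscatter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riceSoS)
```

## The signal

Transplanted paddy rice is the only major land cover whose C-band VH
backscatter traces a V-then-rise curve within one season. At agronomic
flooding the field is a smooth open-water surface: specular reflection
sends the radar energy away from the sensor and sigma-nought drops to its
seasonal minimum (observed between about -22.0 and -17.7 dB). As the crop
tillers and closes canopy, volume scattering raises VH steadily to a peak
at flowering (about -16.1 to -14.2 dB, a rise of 2.7-6.7 dB with a mean
near 5.1 dB over roughly two months), after which drying and senescence
let it decline. Water stays dark all season, built-up areas stay bright
all season, and other vegetation varies gently without the flooding dip.
Two products follow directly from the curve: a rice/non-rice map, and a
per-pixel Start of Season (SoS) dated by the acquisition of minimum dB.

The classifier is a conjunction of seven bounds on that curve
(`classifyPixel`): temporal mean within [a, b] (R1); seasonal variation
within [f, c] (R2); a minimum at or below d falling inside the SoS window
(R3); a post-minimum peak of at least e (R4); a minimum-to-peak duration
inside the growth bounds (R5); consecutive time at or below the flood
threshold no longer than the maximum time underwater (R6); and a peak no
later than the last acquisition (R7). The parameters are not universal
constants: they are re-derived each season from the dB curves of known
rice monitoring fields (`extractRuleParameters`). A conjunction is the
only combination under which each bound keeps its meaning, and ties in
minima and maxima go to the earliest date because SoS is an onset event.

## What the simulator emulates

Real acquisitions of this kind (12-day C-band IW-GRD time series) cannot
be bundled with a package, so the generator (`buildScene`) produces
scenes with known truth that reproduce the statistical features the
classifier actually consumes:

* **Calendar.** 10-20 acquisitions at a 12-day cadence (default: 14
  passes, 9 August to 12 January), with optional missing passes whose
  gaps stay multiples of the cadence.
* **Landscape.** Square fields (default 16 px = 160 m, about 2.6 ha, a
  realistic consolidated paddy block) assigned to rice / other
  vegetation / water / urban with exact largest-remainder pixel counts;
  planting date and curve parameters are drawn per field, because a
  field is transplanted as a unit. Districts are vertical strips: area
  accounting needs labels, not geometry.
* **Rice curves.** Flood minimum uniform on [-22.03, -17.69] dB and peak
  tied to it through a rise drawn uniformly on [3.40, 6.74] dB. The rise
  interval is symmetric about the observed mean rise of 5.07 dB while
  staying inside the observed [2.69, 6.74] dB range; drawing the two
  levels independently would give a mean rise of only 4.71 dB. The dip
  and the peak are realized exactly at their nearest acquisitions - the
  12-day calendar is the native resolution of the product. Two further
  backbone features matter: a puddling level midway between the
  pre-season level and the flood minimum occupies the acquisition before
  transplanting (fields are soaked and levelled before the seedlings go
  in), and the post-peak decline is floored at the senesced-canopy level
  `max(floodMin + 2 dB, -17.5 dB)` - dry-down never takes VH as low as
  open flood water, which is the premise of minimum-dB SoS dating.
* **Noise.** Multiplicative gamma speckle in linear power at 4.4
  equivalent looks (the sensor's stated ENL), plus 0.3 dB additive
  Gaussian variation for environmental effects.
* **Atmospheric anomalies.** Heavy water vapour or rain perturbs single
  acquisitions by +/-6 dB on 5% of (pixel, time) cells
  (`addAtmosphericAnomalies`), never on two consecutive passes of one
  pixel, so a 3-point interpolator can in principle repair every one.
* **Non-rice classes.** Urban -8 dB constant, water -22 dB constant,
  other vegetation near -13 dB with a sub-2.69 dB seasonal half-sine.
  No published dB envelope exists for these at the precision of the rice
  ranges; all levels are configurable stand-ins.

What the simulator does **not** emulate: real field-boundary geometry
(fields are axis-aligned squares), spatially correlated weather (anomaly
cells are independent), terrain and incidence-angle effects (inputs are
assumed normalized), double cropping, and inter-annual calendar shifts.
Passing tests therefore demonstrate that the implementation recovers the
truth of scenes obeying the documented signal model - not that the rule
set would reach the same accuracy over a real delta.

## Preprocessing choices

**Multi-temporal speckle filter.** The operational chains use an optimum
multi-temporal filter whose published description is qualitative, so
`temporalSpeckleFilter` implements a mean-preserving temporal-ratio
surrogate with the same contract: in linear power, output(t) = local
spatial mean at t, rescaled per pixel so the pixel's temporal mean is
preserved exactly. Averaging happens in linear power (physical), while
all thresholds stay in dB (the scale the envelopes are quoted on). The
3x3 default window trades speckle variance (about a 9-fold reduction in
linear variance contributions) against mixing across field boundaries;
a 5x5 window halves the noise again but doubles the boundary band, which
costs more accuracy than it buys on 160 m fields.

**Anomaly interpolation runs after the filter.** `interpolateAnomalies`
repairs interior values that deviate from the mean of their temporal
neighbours by more than a threshold with opposing slopes on both sides.
Ordering matters: on raw ENL-4.4 speckle the dB noise is left-skewed
(gamma in power), and a genuine flooding dip - itself a V-shaped,
single-acquisition feature with a 3-point deviation of 2-3.5 dB - is
then indistinguishable from a trough anomaly; running the interpolator
first measurably erases dips and biases SoS one acquisition late.
After spatial filtering, per-cell anomalies are diluted while genuine
weather-scale deviations (spatially coherent) would survive, which is
what the temporal test should catch. The pipeline default threshold is
4.5 dB: above the flooding-dip deviation, below the 6 dB anomaly scale.
The function's own default stays at a conservative 3 dB for stand-alone
repair of unfiltered series, where the test is applied to already-smooth
signals.

## Parameter extraction

`extractRuleParameters` turns training curves into thresholds by a
min/max envelope widened by a margin (default 0.5 dB): a/b from the
per-signature temporal means (computed in dB), c/f from the
per-signature variations, d from the largest per-signature minimum, e
from the smallest per-signature *post-minimum* peak - the flowering peak
follows flooding, and a pre-season level higher than a weak peak must
not stand in for it. The SoS window and growth-duration bounds are the
observed ranges widened by one acquisition, and the maximum time
underwater is the longest observed run at or below d plus one
acquisition. Widening the margin only relaxes every bound, so a pixel
classified rice can never be lost by increasing it.

Two robustness details:

* Training curves whose post-minimum rise is below 2.69 dB - the
  smallest seedling-to-flowering increase ever observed for rice in this
  system - are excluded before the envelope is formed: their minimum is
  not an agronomic flooding event, and one such curve out of a hundred
  otherwise collapses e, stretches the SoS window and inflates the
  underwater bound. If fewer than three curves pass the screen the
  extractor falls back to the unscreened envelope with a warning, so
  degenerate inputs (e.g. flat series) still yield the literal envelope.
* The flood threshold used by the time-underwater rule is stored
  separately from d (equal at extraction time), so relaxing d for
  sensitivity analysis cannot tighten R6.

Season-length bounds (90-160 days for the main season) are calendar
defaults: a stack that ends before harvest cannot observe them, and they
are carried as metadata rather than enforced by R5, which instead bounds
the observable SoS-to-peak phase.

## Validation design

Ground truth emulates a GPS field survey: points sit at centres of
pixels whose 3x3 neighbourhood is a single class, because surveyors
record fields, not bunds. The 60/40 train/validation split is stratified
by label and fixed before any classification is inspected. Accuracy is
reported as an error matrix (rows mapped, columns reference), overall
accuracy, producer's and user's accuracy per class, and the kappa
coefficient (N A - B)/(N^2 - B); kappa is printed to 2 decimals and
accuracies to 1. Points are assigned to the pixel containing them - no
neighbourhood majority, since none is documented for this workflow.

## Areas and SoS tables

A pixel contributes spacing_x x spacing_y = 10 m x 10 m = 0.01 ha - the
pixel spacing tiles the map without overlap, unlike the larger
resolution cell. Hectares stay at full precision internally and are
rounded to whole hectares only in written tables. District x SoS-date
tables carry exact Total rows/columns, and season bins (early / major /
late planting windows) are per-year calendar inputs, never inferred from
the data; the package ships the published Cauvery Delta zone tables and
per-year bin definitions as reference inputs for the arithmetic checks.

## Problem sizes and determinism

The test suite and the acceptance script run desk-scale scenes: 200 x
200 pixels (4 km x 4 km, 40,000 pixels, 14 acquisitions) for recovery
measurements and 64 x 64 for the pipeline demo - large enough for
stable per-class statistics (24,000 rice pixels) while a full run stays
around a second. Every stochastic step takes an explicit seed;
`runPipeline` derives stage seeds from one master seed, and a rerun with
the same configuration and seed reproduces every raster and table
exactly.

## Known limitations

* Accuracy on simulated scenes (97-98% overall, kappa about 0.95)
  exceeds what the same rules achieve on real imagery (typically high
  80s to low 90s): real landscapes add boundary geometry, calendar
  drift, terrain and class mixtures the generator does not model.
* Classification errors concentrate in the one-pixel band around field
  boundaries, where the spatial window of the filter mixes classes; an
  edge-preserving spatial filter (used by operational chains) is out of
  scope here.
* SoS is quantized to the acquisition calendar; 12 days is the native
  dating precision, and about 9% of rice pixels land one acquisition
  late because the post-flood rise is comparable to residual noise.
* Only VH is simulated and classified; VV and channel ratios carry
  complementary information the rule set does not use.
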