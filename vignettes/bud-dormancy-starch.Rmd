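---
title: "Methods: thermal time, dormancy release and starch densitometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal time, dormancy release and starch densitometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budstarch)
```

`budstarch` models one seasonal story: a dormant flower bud accumulates
cold over winter, breaks endodormancy once its cultivar-specific chilling
requirement is met, and the starch in its ovary primordium rises with
chill and falls with subsequent heat. This vignette documents the models,
their assumptions, the tunable parameters, the synthetic-data generator,
and the numerical and design choices made where the procedure was
genuinely open.

## Thermal-time models

**Utah chill units.** `chill_units_hourly()` maps each hourly temperature
to a piecewise-constant weight; `utah_chill_table()` holds the standard
band table and alternative tables with the same layout can be swapped in.
Bands are half-open with an inclusive lower bound, and temperatures are
used at full floating precision. One consequence of that convention is
that exactly 18.0 °C falls in the −1 band (the band below it covers
[16, 18)); this boundary is measure-zero in real records but is stated
here because band tables are often written with inclusive upper bounds
instead.

Accumulation (`accumulate_thermal()`) is a plain signed running sum over
the window — early-autumn warm hours can push the total negative. Some
practitioners floor the running total at zero instead; since field
records rarely settle the question, both behaviours are available
(`floor_at_zero`, default off) and the default season start is
21 September, configurable.

**Growing degree hours.** `gdh_hourly()` is zero below 6 °C, `T − 4.5`
between 6 and 25 °C, and capped at 20.5 above 25 °C. These three
constants (base, lower threshold, cap) are exposed as arguments. Heat is
accumulated from the dated break of endodormancy; when no bloom date is
supplied, the pipeline reports GDH to the last sampled date.

**Missing hours.** Gaps of at most 3 consecutive hours are filled by
linear interpolation; longer gaps contribute nothing. A window with more
than 5 % missing hours carries a warning and the observed coverage is
stored in the result attributes. Hourly station records are usually far
cleaner than this threshold; the rule exists so that degraded inputs are
visible rather than silently absorbed.

## Dating the break of endodormancy

A forcing test compares bud fresh weights sampled in the field with buds
forced for a week in a warm chamber. The criterion is applied to the
ratio of group means — forced mean at least 30 % above the field mean,
boundary inclusive — rather than per-bud ratios, because the sampling is
destructive: the forced buds are not the same individuals as the field
buds, so only group-level comparison is meaningful. The break date is the
earliest qualifying test; test dates must be strictly increasing but no
particular cadence is assumed. The chilling requirement is then the chill
sum from the season start up to (but not including) the break date's
midnight, so whole days contribute 24 hourly weights each. Chamber
conditions (22 ± 1 °C, 12 h photoperiod, 7 days) are protocol metadata,
not simulated physics.

## Starch densitometry

Images are 8-bit RGB rasters with a known physical pixel size. A pixel
counts as starch when each channel lies within an inclusive `[min, max]`
detection range (`threshold_spec()`), mirroring how interactive image
analysers define a colour as a red/green/blue combination.

**Calibration.** The interactive procedure — raising detection levels
until the binary image matches the granules seen under the microscope —
is replaced by a deterministic optimisation: bounds are restricted to a
quantisation grid (default step 5 intensity levels) and chosen to
maximise intersection-over-union with a reference mask, with ties broken
toward the tightest bounds and then the smallest lower bounds. When the
grid is coarse enough the search is exhaustive over all candidate boxes
(via a 3-D histogram with integral images); otherwise a coordinate ascent
runs exact one-dimensional scans per channel from a full-range start
until a sweep changes nothing. The achieved IoU and the route taken are
recorded on the returned spec. The ascent is not guaranteed to find the
global optimum on adversarial colour distributions, but on stained
sections whose granules occupy a compact colour box it terminates at that
box; the coarse-grid route is tested for exact agreement with a
brute-force oracle.

**Optical density.** The original image analyser's internal OD formula is
unpublished, so the package uses standard transmitted-light densitometry:
greyscale by luma (0.299 R + 0.587 G + 0.114 B) and
OD = log10(255 / max(I, 1)), giving OD 0 for pure white and a ceiling of
log10(255) ≈ 2.41 at the 1-count clamp. Any monotone alternative would
preserve the ordering of measurements; sums would change by a smooth
reparameterisation.

**Frames and aggregation.** The measurement frame is a square of fixed
area (default 1337 µm²; side `round(sqrt(area)/pixel_size)` pixels)
centred on a user-annotated anchor — the simplest shape consistent with a
fixed-area frame, since only the area and a diagram of four measurement
regions are conventionally reported. Four frames are measured per
section and averaged into the ovary value (summing instead of averaging
would only rescale every downstream statistic by 4); six ovaries per
collection date feed the per-date mean ± SD. Anchor placement is
deliberately left to the annotation file: automatic ovary localisation is
out of scope.

**Ovary growth.** Cell walls stained for cellulose appear as bright peaks
along a cross-section transect; `count_cell_layers()` samples the luma
profile at about one-pixel steps with bilinear interpolation and counts
wall peaks (minimum peak distance 3 µm, minimum height 30 % of the
profile range, both configurable), returning peaks − 1 layers. A flat
profile yields zero. `ovary_diameter()` is the Euclidean transect length
times the pixel size.

## Statistics

One-way fixed-effects ANOVA across collection dates is delegated to the
standard linear-model machinery; degenerate layouts (zero within-group
variance with distinct means) are flagged and reported as F = ∞ rather
than an arbitrary large number, and identical data throughout is an
error. Duncan's multiple-range test is implemented in the package:
two means p ranks apart differ when their difference exceeds
R_p = q(γ_p; p, df) · sqrt(MSE/n), with γ_p = (1 − α)^(p−1) and q the
studentized-range quantile from `stats::qtukey` (so no tabulated
approximation is needed). Unbalanced groups use the harmonic-mean n.
Letters mark maximal runs of mutually non-significant ordered means under
the plain pairwise rule — every ordered pair is compared against its own
R_p, without the range-shielding variant — which keeps the display
identical to an exhaustive pairwise oracle and guarantees contiguous
letter runs. By default the test is gated on a significant ANOVA F, as is
conventional; the gate can be lifted.

Pearson correlations use the t transform t = r·sqrt((n−2)/(1−r²)) for
two-sided p-values, with the 0.05/0.01 star convention.
`windowed_correlations()` pairs per-date starch with cumulative chill
units on dates up to and including the break date, and with cumulative
GDH on later dates; windows with fewer than three dates are skipped with
a warning and undefined correlations (constant inputs) are reported as
such per window rather than thrown.

Whether per-date inference should use the six ovary values or the
twenty-four frame values is a design freedom; the package defaults to
per-ovary values (frames within an ovary are pseudo-replicates), and the
per-frame table is written alongside so the alternative is one
`tidyr::pivot_longer()` away.

## The synthetic-data generator

The generator exists so every stage has ground truth. It emulates the
statistical structure the analysis assumes, not histological photorealism
or weather reanalysis.

**Climate.** Hourly temperature from 1 September to 30 April is an
annual sinusoid (12 ± 11 °C, coldest mid-January) plus a ±4 °C diurnal
sinusoid and AR(1) noise (φ = 0.7, marginal SD 1.5 °C), values chosen so
that a ~1000 CU requirement is fulfilled mid-winter, as in continental
cherry-growing climates. A mild winter delays the seasonal curve by
`chill_onset_shift` days (default 20), but only once autumn cooling
reaches ≈13.9 °C daily mean — the level at which the diurnal cycle's
Utah weights sum to zero over a day. Holding the plateau at a
chill-neutral level makes the date of chilling onset shift by almost
exactly the configured amount; shifting the whole curve instead would
drag warm, negative-CU September hours into the accumulation window and
exaggerate the onset difference.

**Forcing tests.** Field weights drift slowly upward; the expected
forced/field ratio is 1.05 before the planted requirement and rises
logistically (width 25 CU) to 1.6 after it, so the 30 % criterion is
crossed within hours of fulfillment, and per-bud noise (SD 3 mg) is
seeded. Weekly tests from 30 November emulate the usual protocol.

**Sections.** Granules are ellipses (semi-axes 2–5 px) in a dark
blue-black RGB band (R 40–90, G 30–70, B 60–110) on a pale textured
background kept strictly outside that band, covering a requested fraction
θ of the four-frame region to within 2 percentage points; the exact mask
is returned, and the band is stored in every bundle's ground truth.
Cell-wall ticks for layer counting are drawn along a horizontal transect.

**Seasonal trajectory.** θ rises linearly in cumulative CU to its peak
(default θ_max = 0.25) at fulfillment and falls linearly in cumulative
GDH, reaching zero after 600 GDH. The depletion scale was set from the
seasonal narrative the package models — starch vanishes during
ecodormancy in the weeks before bud burst, and in these seasons a
mid-winter break accumulates roughly 500–600 GDH by early March. Because
early-ecodormancy GDH accrue slowly, a much larger depletion scale would
plateau the trajectory across several biweekly samples and the observed
maximum would be decided by noise. Per-ovary noise is 10 % of θ_max;
collections run every 14 days from mid-September to the end of March, and
the ovary wall grows from 13 layers (and 90 µm) at fulfillment to about
20 layers (130 µm) as heat accumulates.

**What passing tests do and do not show.** Recovery on these bundles
demonstrates that the implementation is faithful to its own definitions:
the break detector finds a planted requirement, the segmenter recovers a
known mask, correlations recover a planted dependence. Real sections add
stain unevenness, out-of-band granule colours, touching tissues and
focus gradients, and real weather adds fronts and gaps — none of which
the generator emulates — so performance there is bounded by annotation
and calibration quality, not by these tests.

## Problem sizes and determinism

All generators are bit-reproducible for a fixed seed; the pipeline is
deterministic given its inputs, and a config hash plus seed is recorded
in every report. The test suite exercises accumulation against
brute-force oracles on 10⁴-hour random series, requirement recovery on
100 seeded seasons (alternating cold/mild, planted requirements
900–1100 CU, tolerance: the chill accumulated in one 7-day test
interval), 160 × 160 px sections across a 20-point starch gradient, and
50 random 5-group layouts against an exhaustive Duncan oracle — sizes
chosen to exercise every code path at full fidelity while keeping the
default suite under a minute of compute.

## Known limitations

- The Utah table is one convention among several; chill portions
  (Dynamic Model) and Chilling Hours are deliberately out of scope.
- The chilling requirement is a point estimate per cultivar-year;
  aggregation across years or trees (and its dispersion) is left to the
  user.
- Threshold calibration assumes granules occupy a compact colour box;
  stains that bleed continuously into the background will calibrate to a
  compromise box with reported IoU well below 1.
- Cell-layer counting assumes an approximately perpendicular transect
  with resolvable wall peaks; oblique transects overcount spacing and
  may undercount layers.
- One cultivar-year per pipeline invocation; batch layouts are a loop
  over configs by design.
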