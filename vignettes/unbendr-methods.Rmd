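---
title: "Local motion correction with a 3D spline deformation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local motion correction with a 3D spline deformation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unbendr)
```

## The problem

Dose-fractionated cryo-EM movies record the total electron exposure as many
low-exposure frames. The beam moves the sample: a global drift component
(stage and holder instability) plus spatially varying, beam-induced
deformation of the specimen itself, which is most severe for whole cells and
lamellae. Summing frames without correcting both components blurs the
micrograph and destroys high-resolution signal. `unbendr` estimates the full
space-time motion of a movie and resamples every frame so that the average
is sharp.

The pipeline has four stages:

1. **Full-frame alignment.** Each frame is aligned against the
   leave-one-out sum of the other frames by cross-correlation, iterated
   three times with the resolution limit of the correlation relaxed from
   1/2 to 3/4 to the full working Nyquist. Both images are down-weighted by
   `exp(-B s^2 / 4)` with B = 1500 A^2 by default, suppressing
   high-resolution noise that would otherwise dominate the correlation of
   individual low-exposure frames.
2. **Patch alignment.** After global correction, overlapping square patches
   are aligned over frames with the same engine; their trajectories are the
   local deformation residuals at the patch centers.
3. **Least-squares spline fit.** A 3D deformation model — a uniform cubic
   B-spline along the exposure axis, bicubic B-spline surfaces in-plane —
   is fitted to the patch trajectories. Predictions are linear in the knot
   values, so the fit is two exact linear least-squares solves.
4. **Correlation refinement and warping.** The knot values are refined by
   maximizing the summed zero-mean normalized cross-correlation between
   each spline-shifted patch frame and the leave-one-out average of the
   other shifted frames of the same patch stack (L-BFGS with an analytic
   gradient from the Fourier shift theorem). The refined model yields a
   per-pixel displacement field per frame; frames are warped by bilinear
   pull-back sampling and averaged into the corrected micrograph.

## The deformation model

The model stores two sets of knot values, one for x-shifts and one for
y-shifts, on an `NKx x NKy x NKz` grid. Knots are values the spline passes
through; control points are recovered by solving the banded passing system
in which every interior knot satisfies `K = (Q[k] + 4 Q[k+1] + Q[k+2]) / 6`
and the outermost control points satisfy a zero second difference
("free-end"), which makes the spline extend linearly beyond the boundary
knots instead of curling. Surfaces use the tensor-product composition of
the 1D solve along each axis; the matrix segment form

```
S(t) = 1/6 * [t^3 t^2 t 1] M Q,    M = [-1  3 -3  1
                                         3 -6  3  0
                                        -3  0  3  0
                                         1  4  1  0]
```

is verified against the Cox-de Boor recursion in the tests. The model is C2
continuous, reproduces constants and linear fields exactly, and evaluates a
full-frame field as two small matrix products (separable cardinal rows per
axis).

### Grid construction rules

* Patch size: 1024 px below 0.5 A/pixel output sampling, 512 px between
  0.5 and 2.0 A/pixel, above that 512 scaled by the pixel size and rounded
  up to a multiple of 16.
* Patch counts: image dimension / patch size, rounded up — minimal overlap
  with full coverage. Fewer patches enlarge the patch; more patches keep
  the size and overlap more.
* In-plane knots: two-thirds of the patch count per axis (rounded half up),
  at least 4, spread evenly across the image.
* Exposure-axis knots: one knot per 4 e-/A^2 of accumulated exposure,
  `NKz = floor(total/4) + 1` (at least 2) evenly spanning the exposure
  range; a 40-frame movie at 0.4 e-/A^2 per frame gets a knot every
  10 frames. The z coordinate is accumulated exposure expressed in frame
  units, with the first knot at the start of the exposure, so the printed
  spacing is exact.

## Tunable parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `bfactor_initial` | 1500 | A^2 | noise suppression during alignment; outlier re-alignment uses twice this |
| `output_pixel_size` | 1.5 | A/px | working sampling after Fourier cropping |
| `iqr_factor` | 1.5 | — | outlier bound in both alignment stages |
| `sg_window`, `sg_order` | 11, 3 | frames | Savitzky-Golay smoothing of trajectories |
| `knot_exposure_spacing` | 4 | e-/A^2 | z-knot density |
| `min_knots` | 4 | — | in-plane knot floor |
| `max_iter` | 200 | — | L-BFGS cap for the refinement |

Full-frame outliers are frames whose Euclidean deviation from the
Savitzky-Golay curve exceeds `iqr_factor` times the interquartile range of
all deviations (with an absolute floor of 0.05 px, below which deviations
are treated as measurement noise); they are re-aligned with a doubled
B-factor and the re-aligned value is kept only if it lands back within the
bound — otherwise the raw shift is accepted as real (possibly
discontinuous) motion, and smoothing is *not* applied by default. Patch
outliers use the jitter statistic sigma(pi) = sd of the Euclidean
inter-frame steps of a patch trajectory, flagged above `Q3 + 1.5 IQR` and
replaced by the nearest reliable neighbor's whole trajectory.

## Numerical choices

* **Gauge.** A constant shift of all frames is unobservable. Both alignment
  stages use simultaneous (Jacobi) update sweeps, which leave that neutral
  mode where the iteration started; the full-frame trajectory is then
  explicitly zero-meaned over frames. Sequential in-sweep updates would
  drift the constant mode by several pixels on steep trajectories.
* **Subpixel peaks** by separable parabolic fits around the integer
  cross-correlation maximum.
* **Warp direction.** Measured shifts record where content moved *to*;
  correction therefore pull-back samples the input at `p + u(p)` with
  bilinear interpolation. Samples outside the raster take the average
  density of the nearest image edge; the output raster equals the input
  raster.
* **Refinement band limit.** The L2 correlation uses B-factor-weighted
  spectra cropped to half Nyquist; at B = 1500 A^2 and 1.5 A/pixel the
  weight at half Nyquist is below 1e-4, so the crop discards nothing the
  objective can see and quarters the work.
* **Convergence.** L-BFGS stops at a relative objective change of 1e-6 or
  `max_iter` evaluations; the refined parameters are kept only if the
  objective did not worsen.
* **Fourier cropping** truncates beyond the new Nyquist, conserves the
  image mean, and stores the exact realized pixel size
  (`nx * pixel_size / nx_out`).
* **Parameter files** are versioned JSON with doubles printed at 17
  significant digits, so exported models re-import bit-exactly.

## The synthetic test bed

Real validation data for this method are large movie sets plus a full
template-matching engine; the package instead ships a seeded generator
whose ground truth is known exactly:

* 768 x 512 px, 24 frames at 1.5 A/pixel, 1 e-/A^2 per frame;
* 150 Gaussian blobs (sigma 3 px, unit contrast) at seeded subpixel
  positions — dense enough that every 128-px patch holds signal;
* global drift: an exponentially settling trajectory with 6 px peak-to-peak
  range, the familiar fast-early-motion signature of stage drift;
* local deformation: a random in-plane knot pattern with values up to
  6 px, multiplied by a linear exposure ramp;
* per-frame Gaussian noise of sigma 0.3, i.e. a per-frame variance SNR of
  about 0.1, typical of 1 e-/A^2 frames.

Two gauge choices make the truth recoverable in principle. The drift is
zero-mean over frames, and the deformation ramp is exactly zero-mean over
frames, so the clean phantom is the time-mean configuration — the only
reference an alignment method can converge to without external anchors.

The standard fixture uses 128-px patches (`fixture_config()`), giving a
6 x 4 patch grid and the minimum 4 x 4 in-plane knot grid: the 512-px
default patch rule is sized for ~4k-px real micrographs and would
degenerate to a 2 x 1 grid on the small raster. The patch-to-image ratio of
the fixture then matches what the default rules produce at real sizes.

What the generator does *not* emulate: radiation damage (no
exposure-dependent amplitude decay), the contrast transfer function, ice
background structure, and detector artifacts. Passing the recovery tests
therefore demonstrates that the estimator recovers motion of the assumed
smooth space-time form at realistic SNR — not that every property of real
micrographs is handled.

## Accuracy under the standard conditions

With the defaults above, the recovered total motion (global trajectory plus
deformation field) reproduces the truth with a full-raster vector RMSE of
typically 0.35–0.65 px across seeds (median near 0.5 px; unlucky
deformation draws with large boundary-knot values can reach ~1 px), and the
corrected micrograph correlates with the clean phantom consistently better
than the full-frame-only sum.
The error is not uniform: interior pixels are recovered to ~0.1–0.3 px,
while the strips beyond the outermost patch centers (a half-patch inset,
~64 px on the fixture) are extrapolation-determined — the boundary knot
rows sit outside the sampled region, so small measurement errors in the
outermost patches are amplified there. This is an identifiability limit of
patch-based measurement, not of the spline representation: refitting the
model to noise-free patch shifts recovers the field to better than 0.03 px
everywhere. Real micrographs have the same border strips; displacement and
strain values within half a patch of the image edge should be read as
linear extrapolations.

## Strain quantification

From an exported model, `generate_strain_maps()` reconstructs the per-pixel
displacement of any frame against a reference (last vs first frame by
default) and derives the deformation gradient `F = I + grad(u)`, the
Green-Lagrange tensor `E = (F'F - I)/2` — second order in rotation angle,
so rigid rotations drop out — the total equivalent strain
`sqrt(Exx^2 + Eyy^2 + 2 Exy^2)`, and the von Mises equivalent strain built
from the deviatoric tensor with the trace divided by 3. The division by 3
(the three-dimensional convention applied to the in-plane tensor) is kept
deliberately; one consequence, asserted as-is in the tests, is that a pure
in-plane dilation retains a small nonzero von Mises value. Summaries report
strains in percent.

## Problem sizes used by the test suite

Unit tests run on images up to 256 px and movies of 8–10 frames. The
acceptance tests run the full pipeline on the standard 768 x 512 x 24
fixture: once at the default seed for field-recovery accuracy, and across
twenty seeds for the corrected-vs-full-frame comparison. These sizes were
chosen so the whole suite completes in well under half an hour on one CPU
while still exercising every stage at realistic SNR.

## Known limitations

* Per-patch rigid shifts in the refinement stage (matching the patch-wise
  correlation objective) cannot express shear *within* a patch; strong
  sub-patch deformation is only captured after the spline interpolates
  between patches.
* No exposure-dependent frequency weighting of the summed frames
  (dose weighting) — the corrected micrograph is a plain average.
* The model is as good as the patch measurements: patches without contrast
  are detected and replaced by neighbors, but a micrograph dominated by
  featureless ice will degrade gracefully rather than fail loudly.
* Movies are assumed gain-corrected; EER/TIFF containers and
  super-resolution Fourier padding are out of scope.
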