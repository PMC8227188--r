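---
title: "Foveal pit morphometry: models, methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foveal pit morphometry: models, methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foveapit)
```

## The problem

The fovea is a concave depression at the centre of the macula whose
geometry — how deep, wide and steep the pit is — carries clinical and
physiological information.  Optical coherence tomography (OCT) delivers
per-A-scan segmentations of the inner limiting membrane (ILM) and
Bruch's membrane (BM), from which the total retinal thickness

$$\mathrm{TRT}(x, y) = \mathrm{ILM}(x, y) - \mathrm{BM}(x, y)$$

is computed, flattening the eye's curvature against the BM reference.
Two methodological steps in pit morphometry are surprisingly
consequential and are the focus of this package:

1. **Locating the foveal centre.**  Subjects fixate imperfectly, so the
   scan centre can sit a few tenths of a millimetre away from the true
   pit centre.  Because every downstream quantity is computed in a
   centred coordinate frame, centre errors propagate everywhere.
2. **Modelling/smoothing the pit before measuring it.**  Parametric pit
   models and smoothers reduce noise — improving the agreement between
   repeated acquisitions — but also bias the geometry they are supposed
   to measure.

`foveapit` implements the full comparison pipeline: TRT map
construction, four centre-location strategies, resampling to regular
grids and radial profiles, six parametric pit models plus two
smoothers, four geometric pit parameters, and the agreement statistics
(alignment dissimilarity, fitting RMSE, relative bias, ICC(2,1) with
percentile bootstrap, rank-based tests).  Because the kind of paired
raster/star clinical dataset this methodology is aimed at is not
publicly available, the package ships a synthetic OCT acquisition
generator with known ground truth, and every claim the test-suite makes
is made against that generator.

## Data model and conventions

Scans enter through a TSV interchange format (one row per A-scan:
B-scan/A-scan indices, lateral x/y in mm, ILM and BM heights in um over
a flat reference) with a JSON metadata sidecar.  Conventions used
throughout:

* x runs temporal to nasal, y inferior to superior; left eyes are
  mirrored about x = 0 so both lateralities share one frame.
* Angular direction 1 of a radial profile set points along +x (nasal),
  directions proceed counter-clockwise; 24 directions by default.
* Heights are um, lateral coordinates mm; slopes are um/mm with a
  degrees helper (`slope_to_degrees()`), since bias percentages are
  unit-invariant.
* Serialized values carry 6 significant digits — the scanner's 3.87 um
  axial resolution makes finer digits meaningless.

## Resampling scattered thickness data

All resampling goes through one scattered-data interpolant: a C1
Clough–Tocher piecewise cubic on a triangulation of the A-scan
positions.  Each triangle is split at its centroid into three cubic
Bernstein–Bézier patches; vertex values and least-squares vertex
gradients fix the outer control net; cross-edge derivatives are
condensed by forcing the edge-normal derivative to vary linearly along
each edge.  Vertex gradients come from a weighted quadratic
least-squares fit to the triangulation neighbours (linear fallback at
sparse boundary nodes), so the interpolant reproduces affine and
quadratic fields exactly — the test-suite checks both at 1e-6 um.
Queries outside the convex hull are `NA`; nothing is ever extrapolated.

Triangulations are built analytically from the acquisition geometry
(raster: split lattice quads; star: strips between adjacent rays closed
by a central fan), which is exact, deterministic and fast.  Generic
clouds without acquisition indices fall back to a Delaunay
triangulation (`deldir`), escalating a tiny deterministic jitter when
the point set is degenerate; the jitter only affects the triangulation
combinatorics, never the coordinates used for gradients or evaluation.

Two sampling patterns are derived from each centred cloud:

* a **regular grid**, 3 x 3 mm at 0.02 mm spacing (151 x 151), used for
  map-alignment comparisons; undefined cells are skipped pairwise and
  the comparison renormalized by the number of cells actually compared;
* a **radial pattern**, 24 directions by 0 to 2 mm in 0.02 mm steps
  (101 samples), all directions sharing the centre sample, used for
  model fitting and morphometry.  Up to 5% of radial samples may fall
  outside a decentred star field; they are flagged `NA` (beyond 5% the
  scan errors out as too decentred), and the study workflows fill such
  far-field gaps by carrying the last defined sample outward.

## Locating the foveal centre

Four strategies, worded deliberately close to how each is used in
practice:

| method       | definition |
|--------------|------------|
| `none`       | trust fixation; centre = scan centre |
| `min`        | raw A-scan of minimum TRT within the central 0.85 mm *radius* |
| `interp_min` | minimum over a 0.85 x 0.85 mm *square* window resampled to 0.02 mm |
| `smooth_min` | as `interp_min` after a 0.05 mm-radius circular mean filter |

The circle-vs-square asymmetry between `min` and the resampling methods
follows the letter of each method's usual description.  The central
window lattice is centred on the scan centre (43 x 43 nodes at the
defaults, spanning 0.84 mm), which keeps the origin on-lattice; the
0.05 mm kernel on the 0.02 mm lattice is a 21-pixel circular mask,
truncated and renormalized at the window boundary rather than
zero-padded, so constant fields are preserved up to the very edge.
Ties (degenerate flat maps) break deterministically: thickness, then
distance to the scan centre, then acquisition order.

## The pit models

The six parametric families are *reconstructions*: the literature the
families come from describes them by mathematical principle, modelled
region and coefficient count, and the equations below honour those
constraints without claiming numerical equivalence to the original
implementations.

B-scan-region models are fitted per **diametric profile**: radial
direction $k$ is joined with direction $k + 12$ (radii mirrored) to
give 12 two-sided profiles of 201 samples, preserving each model's
two-sided shape assumptions.

* **dubis** (6, per diametric profile): difference of two Gaussians,
  $T(x) = z_0 + A_1 e^{-(x-x_0)^2/2\sigma_1^2} - A_2
  e^{-(x-x_0)^2/2\sigma_2^2}$.  Coefficients are canonicalized to
  $\sigma_1 \ge \sigma_2$ to remove the label-swap ambiguity.
* **ding** (8, one fit for the whole map): quadratic polynomial surface
  minus an axis-aligned elliptical Gaussian.
* **scheibe** (4, per direction): the rise above the centre
  $D(r) = \mu\sigma^2 r^\gamma e^{-\mu r^\gamma} +
  \alpha(1 - e^{-\mu r^\gamma})$ with $D(0) = 0$, i.e. the centre is a
  fixed anchor and the fitted CFT is the raw CFT by construction.
* **liu** (6, per diametric profile): sloped flat bottom with Gaussian
  walls, fitted only between the two detected rims.  The fitted curve
  is still *evaluated* over the full profile, so the model's poor
  behaviour outside its design region shows up honestly in its RMSE
  and rim-radius bias — which is exactly the failure mode practitioners
  report for wide analysis regions.
* **yadav** (2 + 3, per direction): two cubic Bézier segments with
  control abscissae at the segment thirds (so each segment is a cubic
  polynomial in the normalized radius and the free ordinates solve by
  linear least squares).  Endpoints are pinned to the raw centre and
  rim samples; CFT, rim height and rim radius are therefore returned
  as the raw estimates.  The rim *index* is detected on a lightly
  smoothed profile (5-sample moving average) so that a single noisy
  sample cannot become the pinned landmark; the pinned values are the
  raw samples at that index.
* **breher** (9, per diametric profile): sum of three Gaussians.
  Components are canonicalized by decreasing width.  The fit is known
  to be initialization-sensitive; the data-driven default starts from
  a wide base component, a negative central pit component and a broad
  rim mound, which converges reliably on pit-shaped data.

Fitting uses Levenberg–Marquardt least squares (at most 1000
iterations, residual and coefficient tolerances 1e-6) with box
constraints keeping widths positive.  Initial values are data-driven
(offsets from the profile edge mean, amplitudes from rim-centre
differences, widths at fractions of the rim radius); on
non-convergence up to five deterministic restarts perturb the scale
and amplitude coefficients by fixed factors and the lowest-error
solution is kept, with the convergence flag reported honestly either
way.  Non-converged fits are excluded from study summaries and counted.

Two smoothers complete the set, both applied per diametric profile:
LOESS (local quadratic, tricube weights, span 1–50% of the samples —
exact on quadratic profiles) and a centred moving average (5–60
samples, truncated and renormalized at the edges).

## Pit geometry

From a (raw or fitted) radial profile set:

* **CFT** — thickness at radius zero;
* **rim height** — per direction, maximum thickness excluding the
  centre sample (the centre cannot be its own rim);
* **rim radius** — the radius of that maximum; a rim landing exactly on
  the 2 mm boundary is kept but flagged and warned about;
* **maximum slope** — per direction, the largest central-difference
  derivative between centre and rim, in um/mm.

Per-direction values are averaged into one value per parameter and eye.
For anchored models the pinned parameters are copied from the raw
profiles, which renders those cells of the bias/ICC tables as dashes —
the model cannot change what it pins.

## Agreement statistics

* **Alignment dissimilarity** — mean absolute TRT difference between
  the centred raster and star maps of one eye over the shared grid.
* **Fitting RMSE** — root-mean-square difference between raw and fitted
  values.
* **Relative bias** — $100\,(x_\text{model} - x_\text{raw}) /
  x_\text{raw}$; negative means underestimation.
* **ICC(2,1)** — two-way, absolute-agreement, single-measurement
  intraclass correlation by the mean-squares formula
  $(MS_R - MS_E) / (MS_R + (k-1)MS_E + k(MS_C - MS_E)/n)$.  The usual
  naming of this design is inconsistent across nomenclatures
  ("two-way mixed" vs "two-way random"); the formula above is the one
  the (2,1) label conventionally denotes, and the test-suite pins it
  against an independent ANOVA variance-components computation.
* **Percentile bootstrap** — subjects (eyes) are resampled with
  replacement keeping each eye's raster/star pairing intact; 10,000
  resamples and a 95% interval by default, fully seeded.
* **Rank-based tests** — Kruskal–Wallis across methods and pairwise
  Mann–Whitney U (exact for small untied samples, normal approximation
  with tie correction otherwise), flagged at alpha = 0.01, with a
  Shapiro–Wilk normality screen reported per group.

## The synthetic generator

`make_surface()` builds ground truth from the anchored radial family:
the rise above the centre follows $D(r)$ above, with $(\mu, \sigma)$
solved so the surface hits a requested CFT, rim height and rim radius,
and with low-order harmonic modulation of $\mu$ and $\alpha$ in the
polar angle creating nasal/temporal asymmetry.  True per-direction
parameters are computed from the analytic surface on a dense 0.0005 mm
radial lattice and are self-consistent with the package's own
morphometry rules.

`sample_scan()` emulates the two Spectralis-style protocols with a
0.3 mm/degree schematic-eye conversion: raster (25 B-scans x 512
A-scans over 9.0 x 7.5 mm) and star (12 diametric B-scans x 768
A-scans over a 4.5 mm diameter).  Fixation error displaces the pit
relative to the scan centre.  Noise is a per-B-scan correlated Gaussian
field (white noise convolved to a 0.15 mm correlation length, scaled to
2.5 um by default) plus sparse segmentation blips: runs of about five
adjacent A-scans displaced by 25 um with random sign, at an expected
rate of 0.1% of A-scans.  Star acquisitions default to 1.6 times the
raster noise, emulating the visibly noisier star protocol.  Cohort
spreads (CFT 225 +/- 20 um, depth 115 +/- 15 um, rim radius 1.0 +/-
0.15 mm, and so on) are synthetic conventions chosen to be
order-of-magnitude realistic for healthy adult eyes; they are
documented constants of this package, not estimates from any cohort.

What the generator does *not* emulate — reflectivity images, pathology
(hypoplasia, edema), fan-beam display distortion, axial-length lateral
scaling differences — bounds what green tests mean: they validate the
pipeline's internal correctness and the direction of its methodological
effects, not clinical performance on real scans.

A note on interpretation: because the truth surfaces are drawn from the
same family the anchored radial model fits, that model enjoys a
self-family advantage and its fitting error on synthetic cohorts is
lower than a real-data comparison would show.  The fitting-error
ordering asserted in the tests is therefore restricted to the
structural part (flexible per-direction and half-profile fits beat the
rigid whole-map fit), and the bias/agreement conclusions are asserted
directionally, not numerically.

## Numerical choices and degenerate inputs

* Interpolation tolerance: affine/quadratic reproduction to 1e-6 um;
  hull membership decided with a 1e-9 barycentric tolerance.
* The shared centre sample of a radial set is evaluated once and
  assigned to all directions, making the shared-centre invariant exact.
* Collinear clouds, empty centre-search regions, windows exceeding the
  data hull, non-positive thicknesses and zero-variance ICC inputs all
  raise errors naming the offending records.
* Flat maps resolve centre ties deterministically (distance to origin,
  then acquisition order), so reruns are bit-identical.
* All randomness (cohort draws, acquisition noise, bootstrap) is
  seeded; the restart schedule of the fitting engine is deterministic
  by construction, so entire study reports are reproducible
  bit-for-bit.

## Problem sizes

The shipped workflows and checks run on desk-scale cohorts: 50 synthetic
eyes for the study comparisons (the acceptance script), smaller seeded
cohorts (3–12 eyes) for the unit-level workflow tests.  These sizes were
chosen so the full validation cycle completes in minutes while keeping
the cohort large enough for stable medians and rank tests.

## Known limitations

* The six model equations are reconstructions (see above); coefficient
  values are not comparable with the original publications'.
* The star-pattern triangulation assumes diametric B-scans through a
  common crossing point; star-like patterns that do not cross at one
  point would need the generic triangulation path.
* The generic Delaunay fallback (`deldir`) is slow for clouds beyond a
  few thousand points; structured acquisitions avoid it entirely.
* LOESS spans below ~4 samples per window are rejected rather than
  extrapolated, so the practical lower bound of the span range depends
  on the profile length.
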