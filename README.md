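# foveapit

Foveal pit morphometry from OCT retinal thickness data.

The foveal pit is the concave depression at the centre of the macula.
Its geometry — central foveal thickness (CFT), rim height, rim radius
and maximum slope — is measured from optical coherence tomography (OCT)
layer segmentations via the total retinal thickness map,
`TRT = ILM − BM`.  Two methodological steps dominate how reliable those
measurements are, and this package implements and quantifies both:

1. **Foveal centre location.**  Four strategies — trusting fixation
   (`none`), the raw minimum-thickness A-scan (`min`), the minimum on a
   cubically interpolated central grid (`interp_min`), and the minimum
   after circular-kernel smoothing (`smooth_min`) — compared by the
   alignment dissimilarity between paired acquisitions of the same eye,

   D<sub>align</sub> = (1/N²) Σ<sub>i,j</sub> | TRT<sub>raster</sub>[i,j] − TRT<sub>star</sub>[i,j] |.

2. **Pit modelling and smoothing.**  Six parametric models (difference
   of two Gaussians; polynomial surface + Gaussian; an anchored radial
   model based on the second derivative of a Gaussian; a sloped
   piecemeal Gaussian; pinned cubic Bézier curves; a sum of three
   Gaussians) and two smoothers (LOESS, moving average), scored by
   fitting RMSE, by raster–star agreement per parameter (ICC(2,1) with
   a percentile-bootstrap CI), and by the relative estimation bias
   `100 (x_model − x_raw) / x_raw`.

Everything runs on scattered per-A-scan data through a C1
Clough–Tocher piecewise-cubic interpolant (implemented in C++ on
analytically constructed acquisition triangulations), and a synthetic
raster/star scan generator with known ground truth provides the
cohorts the study workflows and the test-suite run on.  The audience is
retinal imaging researchers who need a tested, reproducible pipeline
for pit morphometry methods work.

## Worked example

```r
library(foveapit)

# ground truth: an asymmetric pit, CFT 225 um, rim 340 um at 1 mm
truth <- make_surface(seed = 42)
#> <surface_truth> centre (0.000, 0.000) mm; CFT 225.0 um,
#>   rim 340.0 um at 1.001 mm, max slope 193.3 um/mm

# a raster acquisition with a 0.3 mm fixation error and realistic noise
scan <- sample_scan(truth, acquisition_config(
  "raster", decenter_mm = c(0.30, -0.10), noise_sd_um = 2.5, seed = 1))

cloud  <- compute_trt(scan)
center <- locate_center(cloud, "smooth_min")
#> <fovea_center> (0.2800, -0.0600) mm by method "smooth_min"

profiles <- resample_radial(recenter(cloud, center))
compute_parameters(profiles)
#> <pit_params> (raw, 24 directions)
#>   CFT 224.3 um | rim height 339.7 um | rim radius 1.017 mm |
#>   max slope 195.4 um/mm (11.1 deg)

fit <- fit_model(profiles, model_spec("scheibe"))
#> <pit_fit> scheibe: rmse 1.119 um, converged (max 7 iterations)

model_params <- parameters_from_fit(fit, profiles)
#> <pit_params> (scheibe, 24 directions)
#>   CFT 224.3 um | rim height 339.0 um | rim radius 1.016 mm |
#>   max slope 189.6 um/mm (10.7 deg)

relative_bias(model_params$mean_max_slope_um_mm,
              compute_parameters(profiles)$mean_max_slope_um_mm)
#> [1] -2.949493
```

Reading the output: the smoothed-minimum search recovers the simulated
0.30/−0.10 mm fixation error to within 0.04 mm; the raw radial profiles
reproduce the true geometry (CFT 225, rim 340 um at 1.0 mm) to within
the sampling lattice; the anchored radial model fits the noisy
profiles with a 1.1 um RMSE, leaves the CFT untouched by construction,
and underestimates the maximum slope by about 3% — the
agreement-versus-bias trade-off the study workflows quantify at cohort
scale.

Cohort-level workflows:

```r
cohort <- make_cohort(50, seed = 7)          # paired raster/star eyes
cc <- run_center_comparison(cohort)          # Dalign per centre method
mc <- run_model_comparison(cohort)           # RMSE / ICC / bias tables
```

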