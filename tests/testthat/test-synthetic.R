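test_that("surfaces are deterministic under a seed and self-consistent", {
  t1 <- make_surface(seed = 10)
  t2 <- make_surface(seed = 10)
  t3 <- make_surface(seed = 11)
  expect_equal(t1$true_params, t2$true_params)
  expect_equal(t1$shape$modulation, t2$shape$modulation)
  expect_false(identical(t1$shape$modulation, t3$shape$modulation))
  # requested geometry is honoured by the dense numeric evaluation
  expect_equal(t1$true_params$cft_um, 225, tolerance = 1e-6)
  expect_lt(abs(mean(t1$true_params$rim_height_um) - 340), 1.5)
  expect_lt(abs(mean(t1$true_params$rim_radius_mm) - 1.0), 0.05)
})

test_that("zero modulation gives identical per-direction parameters", {
  t0 <- make_surface(list(modulation = list(mu_cos = 0, mu_sin = 0,
                                            mu_cos2 = 0, alpha_cos = 0)))
  expect_equal(length(unique(round(t0$true_params$rim_radius_mm, 10))), 1L)
  expect_equal(length(unique(round(t0$true_params$rim_height_um, 8))), 1L)
  expect_equal(t0$true_params$rim_height_um[1L], 340, tolerance = 1e-4)
  expect_equal(t0$true_params$rim_radius_mm[1L], 1.0, tolerance = 5e-4)
})

test_that("thickness scaling scales heights and slopes but not the radius", {
  mod0 <- list(mu_cos = 0.04, mu_sin = -0.02, mu_cos2 = 0.03,
               alpha_cos = 0.02)
  a <- make_surface(list(modulation = mod0))
  b <- make_surface(list(cft_um = 225 * 1.2, rim_height_um = 340 * 1.2,
                         modulation = mod0))
  expect_equal(b$true_params$cft_um, 1.2 * a$true_params$cft_um,
               tolerance = 1e-6)
  expect_equal(b$true_params$rim_height_um,
               1.2 * a$true_params$rim_height_um, tolerance = 1e-5)
  expect_equal(b$true_params$max_slope_um_mm,
               1.2 * a$true_params$max_slope_um_mm, tolerance = 1e-4)
  expect_equal(b$true_params$rim_radius_mm, a$true_params$rim_radius_mm,
               tolerance = 1e-6)
})

test_that("degenerate shape requests are rejected", {
  expect_error(make_surface(list(rim_height_um = 200)), "no pit")
  expect_error(make_surface(list(alpha_frac = 1.2)), "alpha_frac")
})

test_that("noise-free acquisitions sample the surface exactly", {
  truth <- make_surface(seed = 2)
  sc <- sample_scan(truth, acquisition_config("raster", noise_sd_um = 0,
                                              blip_rate = 0))
  expect_equal(nrow(sc$data), 12800L)
  cl <- compute_trt(sc)
  expect_equal(cl$trt_um, truth$fn(cl$x_mm, cl$y_mm), tolerance = 1e-12)

  st <- sample_scan(truth, acquisition_config("star", noise_sd_um = 0,
                                              blip_rate = 0))
  expect_equal(nrow(st$data), 12L * 768L)
  cls <- compute_trt(st)
  expect_equal(cls$trt_um, truth$fn(cls$x_mm, cls$y_mm), tolerance = 1e-12)

  expect_error(sample_scan(truth, acquisition_config(
    "star", decenter_mm = c(0.9, 0))), "outside")
})

test_that("the full pipeline recovers true parameters on clean centred scans", {
  # the star protocol samples every radial direction densely along its
  # diameters, so lattice tolerances apply in all 24 directions
  truth <- make_surface(seed = 4)
  sc <- sample_scan(truth, acquisition_config("star", noise_sd_um = 0,
                                              blip_rate = 0))
  cl <- compute_trt(sc)
  ctr <- locate_smooth_min(cl)
  prof <- resample_radial(recenter(cl, ctr))
  p <- compute_parameters(prof)
  tp <- truth$true_params
  expect_lt(abs(p$cft_um - tp$cft_um), 0.5)
  expect_lt(max(abs(p$rim_height_um - tp$rim_height_um)), 0.5)
  expect_lte(max(abs(p$rim_radius_mm - tp$rim_radius_mm)), 0.02 + 1e-9)
  expect_lt(max(abs(p$max_slope_um_mm - tp$max_slope_um_mm) /
                  tp$max_slope_um_mm), 0.01)
})

test_that("a decentred clean scan is re-centred by smooth + min", {
  truth <- make_surface(list(modulation = list(
    mu_cos = 0.05, mu_sin = 0.02, mu_cos2 = -0.03, alpha_cos = 0.03)))
  sc <- sample_scan(truth, acquisition_config(
    "raster", decenter_mm = c(0.35, 0), noise_sd_um = 0, blip_rate = 0))
  ctr <- locate_smooth_min(compute_trt(sc))
  expect_lt(abs(ctr$x_mm - 0.35), 0.03)
  expect_lt(abs(ctr$y_mm - 0), 0.03)
})

test_that("cohorts are seeded, pair-structured and spread-controllable", {
  c1 <- make_cohort(4, seed = 21)
  c2 <- make_cohort(4, seed = 21)
  expect_identical(c1[[3]]$raster$data, c2[[3]]$raster$data)
  expect_identical(c1[[2]]$star$data, c2[[2]]$star$data)
  expect_equal(length(c1), 4L)
  expect_s3_class(c1[[1]]$raster, "oct_scan")
  expect_s3_class(c1[[1]]$star, "oct_scan")

  c0 <- make_cohort(3, between_subject_sd = 0, seed = 5)
  expect_equal(c0[[1]]$truth$true_params, c0[[3]]$truth$true_params)
})

test_that("matched noise settings make raster and star residuals comparable", {
  truth <- make_surface(list(modulation = list(mu_cos = 0, mu_sin = 0,
                                               mu_cos2 = 0, alpha_cos = 0)))
  resid_sd <- function(pattern, seed) {
    sc <- sample_scan(truth, acquisition_config(
      pattern, noise_sd_um = 2.5, blip_rate = 0, seed = seed))
    cl <- compute_trt(sc)
    sd(cl$trt_um - truth$fn(cl$x_mm, cl$y_mm))
  }
  s_r <- resid_sd("raster", 31)
  s_s <- resid_sd("star", 32)
  # same configured noise: spreads agree within a few percent
  expect_lt(abs(s_r - s_s) / s_r, 0.1)
  # scaled noise scales the residual spread
  truth2 <- truth
  sc2 <- sample_scan(truth2, acquisition_config(
    "star", noise_sd_um = 5, blip_rate = 0, seed = 32))
  cl2 <- compute_trt(sc2)
  expect_equal(sd(cl2$trt_um - truth2$fn(cl2$x_mm, cl2$y_mm)) / s_s, 2,
               tolerance = 0.05)
})
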