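test_that("the no-op strategy always returns the scan centre", {
  pit <- function(x, y) 300 - 80 * exp(-((x - 0.3)^2 + (y + 0.2)^2) / 0.05)
  ctr <- locate_none(lattice_cloud(pit))
  expect_equal(c(ctr$x_mm, ctr$y_mm), c(0, 0))
  expect_identical(ctr$method, "none")
})

test_that("locate_min finds the raw minimum inside the circular region", {
  # pit minimum placed exactly on a sampled A-scan
  nx <- 101L; ny <- 41L
  xs <- seq(-2.5, 2.5, length.out = nx)  # 0.05 spacing: 0.30 on-lattice
  ys <- seq(-2, 2, length.out = ny)      # 0.10 spacing: -0.20 on-lattice
  pit <- function(x, y) 300 - 80 * exp(-((x - 0.30)^2 + (y + 0.20)^2) / 0.08)
  x <- rep(xs, ny); y <- rep(ys, each = nx)
  cl <- trt_cloud(x, y, pit(x, y))
  ctr <- locate_min(cl)
  # brute-force oracle over the same region
  inside <- x^2 + y^2 <= 0.85^2
  i_best <- which(inside)[which.min(pit(x, y)[inside])]
  expect_equal(c(ctr$x_mm, ctr$y_mm), c(x[i_best], y[i_best]))
  expect_equal(c(ctr$x_mm, ctr$y_mm), c(0.30, -0.20))

  # ties break towards the scan centre
  cl2 <- trt_cloud(c(0.1, 0.5, 0.7), c(0, 0, 0.2), c(200, 200, 260))
  ctr2 <- locate_min(cl2)
  expect_equal(c(ctr2$x_mm, ctr2$y_mm), c(0.1, 0))

  # empty search region
  cl3 <- trt_cloud(c(1, 1.5, -2), c(1, 0.3, 1), c(250, 240, 260))
  expect_error(locate_min(cl3), "search region")
})

test_that("interpolated minimum recovers off-lattice pit centres to grid accuracy", {
  pit <- function(x, y)
    300 - 80 * exp(-((x - 0.113)^2 + (y + 0.207)^2) / 0.06)
  cl <- lattice_cloud(pit, nx = 160L, ny = 41L, hx = 3, hy = 2)
  ctr <- locate_interp_min(cl)
  # fine-lattice brute-force oracle on the analytic surface
  fine <- seq(-0.425, 0.425, by = 0.0005)
  fg <- expand.grid(x = fine, y = fine)
  i_best <- which.min(pit(fg$x, fg$y))
  expect_lt(abs(ctr$x_mm - fg$x[i_best]), 0.02 + 1e-12)
  expect_lt(abs(ctr$y_mm - fg$y[i_best]), 0.02 + 1e-12)

  # constant map: origin by tie-break
  flat <- lattice_cloud(function(x, y) rep(250, length(x)))
  c0 <- locate_interp_min(flat)
  expect_equal(c(c0$x_mm, c0$y_mm), c(0, 0))

  # window exceeding the data hull
  tiny <- scatter_cloud(function(x, y) 250 + x^2, n = 150L, half = 0.3)
  expect_error(locate_interp_min(tiny), "hull")
})

test_that("the circular smoothing kernel covers 21 pixels at the default scales", {
  # 0.05 mm radius on a 0.02 mm lattice: offsets with norm <= 2.5 px
  offs <- expand.grid(di = -3:3, dj = -3:3)
  expect_equal(sum(offs$di^2 + offs$dj^2 <= 2.5^2), 21L)
  # constant field is unchanged by the filter (mean-preserving, edges included)
  v <- matrix(7, 43L, 43L)
  expect_equal(foveapit:::circular_mean_filter(v, 2.5), v)
  # linear ramps pass through in the window interior
  ramp <- matrix(rep(seq_len(43L), 43L), 43L)
  sm <- foveapit:::circular_mean_filter(ramp, 2.5)
  expect_equal(sm[10:34, 10:34], ramp[10:34, 10:34])
})

test_that("smoothing makes the minimum robust to a single-pixel notch", {
  # shallow pit: the 40 um notch 0.4 mm off-centre undercuts the true
  # minimum for the raw search but not for the smoothed one
  pit <- function(x, y) 300 - 30 * exp(-(x^2 + y^2) / 0.08)
  nx <- 160L; ny <- 41L
  xs <- seq(-3, 3, length.out = nx); ys <- seq(-2, 2, length.out = ny)
  x <- rep(xs, ny); y <- rep(ys, each = nx)
  v <- pit(x, y)
  # spurious 40 um notch 0.4 mm off-centre, on a sampled A-scan
  i_notch <- which.min((x - 0.4)^2 + y^2)
  v[i_notch] <- v[i_notch] - 40
  cl <- trt_cloud(x, y, v,
                  bscan_index = rep(seq_len(ny) - 1L, each = nx),
                  ascan_index = rep(seq_len(nx) - 1L, ny),
                  meta = scan_meta("raster", n_bscans = ny, n_ascans = nx))
  c_min <- locate_min(cl)
  c_smooth <- locate_smooth_min(cl)
  expect_gt(sqrt(c_min$x_mm^2 + c_min$y_mm^2), 0.3)     # follows the notch
  expect_lt(sqrt(c_smooth$x_mm^2 + c_smooth$y_mm^2), 0.05)  # ignores it
})

test_that("the dispatcher routes to the strategies and rejects unknown ones", {
  pit <- function(x, y) 300 - 80 * exp(-(x^2 + y^2) / 0.08)
  cl <- lattice_cloud(pit)
  c1 <- locate_center(cl, "none")
  expect_equal(c(c1$x_mm, c1$y_mm), c(0, 0))
  c2 <- locate_center(cl, "smooth_min")
  c2_direct <- locate_smooth_min(cl)
  expect_equal(c2, c2_direct)
  expect_error(locate_center(cl, "centroid"), "unknown")
})

test_that("noise-free decentred pits are localized within spec tolerances", {
  for (dec in list(c(0.2, 0.1), c(-0.35, 0.25), c(0.4, 0))) {
    truth <- make_surface(list(modulation = list(
      mu_cos = 0.05, mu_sin = 0, mu_cos2 = 0.03, alpha_cos = 0.02)))
    sc <- sample_scan(truth, acquisition_config(
      "raster", decenter_mm = dec, noise_sd_um = 0, blip_rate = 0))
    cl <- compute_trt(sc)
    for (m in c("interp_min", "smooth_min")) {
      ctr <- locate_center(cl, m)
      # within 1.5 grid cells of the true centre
      expect_lte(abs(ctr$x_mm - dec[1L]), 0.03 + 1e-9)
      expect_lte(abs(ctr$y_mm - dec[2L]), 0.03 + 1e-9)
    }
    ctr_min <- locate_min(cl)
    # raw-minimum error bounded by the native A-scan spacing (y: 0.3125)
    expect_lt(abs(ctr_min$x_mm - dec[1L]), 9 / 511 + 1e-9)
    expect_lt(abs(ctr_min$y_mm - dec[2L]), 7.5 / 24 + 1e-9)
  }
})
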