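# Fixtures built in code: small scans, analytic clouds and profile sets.

# a tiny valid scan: nb B-scans x na A-scans on a raster lattice with an
# analytic thickness surface
toy_scan <- function(nb = 2L, na = 6L, fn = function(x, y) 250 + 10 * x - 5 * y,
                     eye = "OD") {
  xs <- seq(-1, 1, length.out = na)
  ys <- seq(-0.5, 0.5, length.out = nb)
  d <- data.frame(
    bscan_index = rep(seq_len(nb) - 1L, each = na),
    ascan_index = rep(seq_len(na) - 1L, nb),
    x_mm = rep(xs, nb), y_mm = rep(ys, each = na))
  d$ilm_um <- fn(d$x_mm, d$y_mm)
  d$bm_um <- 0
  oct_scan(scan_meta("raster", eye = eye, n_bscans = nb, n_ascans = na), d)
}

# a raster-lattice cloud over [-hx, hx] x [-hy, hy] evaluating fn
lattice_cloud <- function(fn, nx = 60L, ny = 25L, hx = 4.5, hy = 3.75) {
  xs <- seq(-hx, hx, length.out = nx)
  ys <- seq(-hy, hy, length.out = ny)
  x <- rep(xs, ny); y <- rep(ys, each = nx)
  trt_cloud(x, y, fn(x, y),
            bscan_index = rep(seq_len(ny) - 1L, each = nx),
            ascan_index = rep(seq_len(nx) - 1L, ny),
            meta = scan_meta("raster", n_bscans = ny, n_ascans = nx))
}

# scattered random cloud (generic triangulation path)
scatter_cloud <- function(fn, n = 400L, half = 2.5, seed = 1L) {
  set.seed(seed)
  x <- runif(n, -half, half); y <- runif(n, -half, half)
  trt_cloud(x, y, fn(x, y))
}

# analytic radially symmetric pit used across morphometry tests
analytic_pit <- function(x, y) {
  r2 <- x^2 + y^2
  250 + 100 * (1 - exp(-r2 / 0.18)) - 100 * exp(-r2 / 0.02)
}

# a complete noise-free radial profile set from an analytic radial fn
analytic_profiles <- function(fr, n_directions = 24L, radius = 2.0,
                              step = 0.02) {
  radii <- seq(0, radius, by = step)
  angles <- 2 * pi * (seq_len(n_directions) - 1L) / n_directions
  vals <- matrix(rep(fr(radii), each = n_directions), n_directions)
  radial_profiles(angles, radii, vals)
}

# profile set evaluating a direction-dependent surface f(r, theta)
surface_profiles <- function(f2, n_directions = 24L, radius = 2.0,
                             step = 0.02) {
  radii <- seq(0, radius, by = step)
  angles <- 2 * pi * (seq_len(n_directions) - 1L) / n_directions
  vals <- t(vapply(angles, function(a) f2(radii, a), numeric(length(radii))))
  vals[, 1L] <- vals[1L, 1L]
  radial_profiles(angles, radii, vals)
}

# brute-force ICC(2,1) via two-way ANOVA variance components
icc_oracle <- function(pairs) {
  pairs <- as.matrix(pairs)
  n <- nrow(pairs); k <- ncol(pairs)
  df <- data.frame(y = as.vector(pairs),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- anova(aov(y ~ subject + rater, data = df))[["Mean Sq"]]
  msr <- ms[1L]; msc <- ms[2L]; mse <- ms[3L]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
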