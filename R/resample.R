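#' Regular-grid TRT map
#'
#' A square lattice of interpolated thickness values centred on the
#' origin, the working representation for map alignment comparisons.
#' Cells outside the convex hull of the source data are `NA`.
#'
#' @param x_axis,y_axis Strictly increasing, uniformly spaced coordinates
#'   in mm.
#' @param values_um Matrix of thicknesses with `length(y_axis)` rows and
#'   `length(x_axis)` columns (row = y, column = x).
#' @param spacing_mm Lattice spacing in mm.
#' @return An object of class `trt_grid`.
#' @export
trt_grid <- function(x_axis, y_axis, values_um, spacing_mm) {
  check_axis <- function(a, nm) {
    if (length(a) > 1L && any(abs(diff(a) - spacing_mm) > 1e-12))
      stop(nm, " is not uniform at the stated spacing", call. = FALSE)
  }
  check_axis(x_axis, "x_axis"); check_axis(y_axis, "y_axis")
  values_um <- as.matrix(values_um)
  if (nrow(values_um) != length(y_axis) || ncol(values_um) != length(x_axis))
    stop("values_um must be length(y_axis) x length(x_axis)", call. = FALSE)
  structure(list(x_axis = x_axis, y_axis = y_axis, values_um = values_um,
                 spacing_mm = spacing_mm, n = length(x_axis)),
            class = "trt_grid")
}

#' @export
print.trt_grid <- function(x, ...) {
  cat(sprintf("<trt_grid> %d x %d at %.3g mm, x/y in [%.3g, %.3g] mm, %d undefined cell(s)\n",
              nrow(x$values_um), ncol(x$values_um), x$spacing_mm,
              min(x$x_axis), max(x$x_axis), sum(is.na(x$values_um))))
  invisible(x)
}

#' @export
as.data.frame.trt_grid <- function(x, ...) {
  data.frame(x_mm = rep(x$x_axis, each = length(x$y_axis)),
             y_mm = rep(x$y_axis, length(x$x_axis)),
             trt_um = as.vector(x$values_um))
}

#' Resample a TRT cloud to a regular grid
#'
#' Interpolates the scattered thickness samples onto a square lattice of
#' total side `extent_mm` centred on the origin (so run [recenter()]
#' first if the foveal centre should sit at the grid centre), using the
#' triangulation-based C1 piecewise-cubic scheme.  Cells outside the
#' convex hull of the cloud are left `NA`, never extrapolated.
#'
#' @param cloud A [trt_cloud()].
#' @param extent_mm Total side length of the grid in mm (default 3.0).
#' @param spacing_mm Lattice spacing in mm (default 0.02, giving a
#'   151 x 151 map at the default extent).
#' @return A [trt_grid()].
#' @export
resample_regular <- function(cloud, extent_mm = 3.0, spacing_mm = 0.02) {
  stopifnot(inherits(cloud, "trt_cloud"))
  half <- extent_mm / 2
  ax <- seq(-half, half, by = spacing_mm)
  itp <- cloud_interpolant(cloud)
  qx <- rep(ax, each = length(ax))   # column-major over (y, x)
  qy <- rep(ax, length(ax))
  v <- matrix(interp_at(itp, qx, qy), nrow = length(ax), ncol = length(ax))
  trt_grid(ax, ax, v, spacing_mm)
}

#' Radial TRT profile set
#'
#' Thickness sampled along `n_directions` rays from the (recentred)
#' foveal centre.  All rays share the sample at radius zero.
#'
#' @param angles_rad Ray directions in radians; direction 1 points along
#'   +x (nasal), counter-clockwise.
#' @param radii_mm Radial sample positions, starting at exactly 0.
#' @param values_um Matrix `length(angles_rad)` x `length(radii_mm)`.
#' @param center The [fovea_center()] the cloud was recentred on, if any.
#' @return An object of class `radial_profiles`.
#' @export
radial_profiles <- function(angles_rad, radii_mm, values_um, center = NULL) {
  values_um <- as.matrix(values_um)
  if (nrow(values_um) != length(angles_rad) ||
      ncol(values_um) != length(radii_mm))
    stop("values_um must be n_directions x n_radii", call. = FALSE)
  if (radii_mm[1L] != 0)
    stop("radii must start at exactly 0", call. = FALSE)
  v0 <- values_um[, 1L]
  if (length(unique(v0[!is.na(v0)])) > 1L)
    stop("all directions must share the centre sample", call. = FALSE)
  structure(list(angles_rad = angles_rad, radii_mm = radii_mm,
                 values_um = values_um, center = center),
            class = "radial_profiles")
}

#' @export
print.radial_profiles <- function(x, ...) {
  cat(sprintf("<radial_profiles> %d directions x %d radii (0 to %.3g mm), %d undefined sample(s)\n",
              length(x$angles_rad), length(x$radii_mm), max(x$radii_mm),
              sum(is.na(x$values_um))))
  invisible(x)
}

#' @export
as.data.frame.radial_profiles <- function(x, ...) {
  data.frame(direction = rep(seq_along(x$angles_rad), length(x$radii_mm)),
             angle_rad = rep(x$angles_rad, length(x$radii_mm)),
             radius_mm = rep(x$radii_mm, each = length(x$angles_rad)),
             trt_um = as.vector(x$values_um))
}

#' Resample a recentred TRT cloud to a radial pattern
#'
#' Samples the thickness surface along `n_directions` uniformly spaced
#' rays from the origin out to `radius_mm`, by the same piecewise-cubic
#' interpolation used for [resample_regular()].  The cloud must already
#' be recentred so that the located foveal centre lies at the origin.
#' Samples outside the data hull are flagged `NA`; if they exceed 5% of
#' all samples the scan is considered too decentred and an error is
#' raised.
#'
#' @param cloud A recentred [trt_cloud()].
#' @param radius_mm Profile length in mm (default 2.0).
#' @param n_directions Number of angular directions (default 24).
#' @param step_mm Radial spacing in mm (default 0.02, so 101 samples).
#' @return A [radial_profiles()].
#' @export
resample_radial <- function(cloud, radius_mm = 2.0, n_directions = 24L,
                            step_mm = 0.02) {
  stopifnot(inherits(cloud, "trt_cloud"))
  angles <- 2 * pi * (seq_len(n_directions) - 1L) / n_directions
  radii <- seq(0, radius_mm, by = step_mm)
  itp <- cloud_interpolant(cloud)
  qx <- as.vector(outer(angles, radii, function(a, r) r * cos(a)))
  qy <- as.vector(outer(angles, radii, function(a, r) r * sin(a)))
  v <- matrix(interp_at(itp, qx, qy), nrow = n_directions)
  v[, 1L] <- v[1L, 1L]  # exact shared centre sample
  frac_na <- mean(is.na(v))
  if (frac_na > 0.05)
    stop(sprintf("%.1f%% of radial samples fall outside the data hull: scan too decentered",
                 100 * frac_na), call. = FALSE)
  radial_profiles(angles, radii, v,
                  center = attr(cloud, "center"))
}
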