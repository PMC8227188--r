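#' Foveal centre estimate
#'
#' @param x_mm,y_mm Centre coordinates in mm, scan centre at the origin.
#' @param method The strategy that produced the estimate: `"none"`,
#'   `"min"`, `"interp_min"` or `"smooth_min"`.
#' @return An object of class `fovea_center`.
#' @export
fovea_center <- function(x_mm, y_mm,
                         method = c("none", "min", "interp_min", "smooth_min")) {
  method <- match.arg(method)
  stopifnot(is.finite(x_mm), is.finite(y_mm))
  structure(list(x_mm = as.numeric(x_mm), y_mm = as.numeric(y_mm),
                 method = method), class = "fovea_center")
}

#' @export
print.fovea_center <- function(x, ...) {
  cat(sprintf("<fovea_center> (%.4f, %.4f) mm by method \"%s\"\n",
              x$x_mm, x$y_mm, x$method))
  invisible(x)
}

#' Assume the scan centre as the foveal centre
#'
#' The no-op strategy: trusts subject fixation during acquisition and
#' returns the origin regardless of the data.
#'
#' @param cloud A [trt_cloud()] (ignored).
#' @return A [fovea_center()] at (0, 0).
#' @export
locate_none <- function(cloud) fovea_center(0, 0, "none")

#' Foveal centre at the raw A-scan of minimum thickness
#'
#' Searches the A-scans inside the central circular region and returns
#' the coordinates of the one with minimum TRT.  Ties are broken by
#' distance to the scan centre, then by acquisition order, so the result
#' is deterministic on flat inputs.
#'
#' @param cloud A [trt_cloud()].
#' @param region_radius_mm Radius of the circular search region (default
#'   0.85 mm).
#' @return A [fovea_center()].
#' @export
locate_min <- function(cloud, region_radius_mm = 0.85) {
  stopifnot(inherits(cloud, "trt_cloud"))
  r2 <- cloud$x_mm^2 + cloud$y_mm^2
  inside <- which(r2 <= region_radius_mm^2)
  if (!length(inside))
    stop("no A-scans inside the central search region", call. = FALSE)
  sub <- cloud[inside, , drop = FALSE]
  o <- order(sub$trt_um, r2[inside],
             if (!is.null(sub$bscan_index)) sub$bscan_index else seq_len(nrow(sub)),
             if (!is.null(sub$ascan_index)) sub$ascan_index else seq_len(nrow(sub)))
  best <- o[1L]
  fovea_center(sub$x_mm[best], sub$y_mm[best], "min")
}

# central square lattice used by the resampling-based strategies:
# centred on the scan centre, 0.02 mm cells, covering the window
center_window_axis <- function(window_mm, spacing_mm) {
  k <- floor(window_mm / 2 / spacing_mm)
  (-k:k) * spacing_mm
}

grid_minimum <- function(ax, values) {
  # deterministic argmin: thickness (values within 1e-9 um count as
  # tied, so interpolation round-off cannot defeat the tie rule), then
  # distance to origin, then row-major order
  gx <- rep(ax, each = length(ax)); gy <- rep(ax, length(ax))
  v <- as.vector(values)
  ok <- which(is.finite(v))
  if (!length(ok)) stop("central window holds no defined values", call. = FALSE)
  tied <- ok[v[ok] <= min(v[ok]) + 1e-9]
  o <- tied[order(gx[tied]^2 + gy[tied]^2, tied)]
  c(gx[o[1L]], gy[o[1L]])
}

resample_center_window <- function(cloud, window_mm, spacing_mm) {
  ax <- center_window_axis(window_mm, spacing_mm)
  itp <- cloud_interpolant(cloud)
  qx <- rep(ax, each = length(ax)); qy <- rep(ax, length(ax))
  v <- interp_at(itp, qx, qy)
  if (anyNA(v))
    stop("central window exceeds the data hull", call. = FALSE)
  list(ax = ax, values = matrix(v, length(ax), length(ax), byrow = TRUE))
}

#' Foveal centre on an interpolated central grid
#'
#' Resamples the central square window of the TRT map to a fine regular
#' lattice by cubic interpolation and returns the lattice point of
#' minimum thickness.
#'
#' @param cloud A [trt_cloud()].
#' @param window_mm Side of the central square window (default 0.85 mm).
#' @param spacing_mm Lattice spacing (default 0.02 mm).
#' @return A [fovea_center()].
#' @export
locate_interp_min <- function(cloud, window_mm = 0.85, spacing_mm = 0.02) {
  stopifnot(inherits(cloud, "trt_cloud"))
  w <- resample_center_window(cloud, window_mm, spacing_mm)
  xy <- grid_minimum(w$ax, t(w$values))
  fovea_center(xy[1L], xy[2L], "interp_min")
}

# circular-support mean filter, truncated and renormalized at the window
# boundary (no zero padding bias)
circular_mean_filter <- function(values, radius_px) {
  offs <- expand.grid(di = -floor(radius_px):floor(radius_px),
                      dj = -floor(radius_px):floor(radius_px))
  offs <- offs[offs$di^2 + offs$dj^2 <= radius_px^2, ]
  n <- nrow(values); m <- ncol(values)
  acc <- matrix(0, n, m); cnt <- matrix(0, n, m)
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    si <- max(1L, 1L - di):min(n, n - di)
    sj <- max(1L, 1L - dj):min(m, m - dj)
    acc[si, sj] <- acc[si, sj] + values[si + di, sj + dj]
    cnt[si, sj] <- cnt[si, sj] + 1
  }
  acc / cnt
}

#' Foveal centre on a smoothed interpolated central grid
#'
#' As [locate_interp_min()], but the resampled central window is first
#' smoothed with a circular-kernel mean filter, which makes the minimum
#' robust to single-A-scan segmentation blips.
#'
#' @inheritParams locate_interp_min
#' @param kernel_radius_mm Radius of the circular filter support
#'   (default 0.05 mm; with the default 0.02 mm lattice this is a
#'   21-pixel mask).
#' @return A [fovea_center()].
#' @export
locate_smooth_min <- function(cloud, window_mm = 0.85, spacing_mm = 0.02,
                              kernel_radius_mm = 0.05) {
  stopifnot(inherits(cloud, "trt_cloud"))
  w <- resample_center_window(cloud, window_mm, spacing_mm)
  sm <- circular_mean_filter(w$values, kernel_radius_mm / spacing_mm)
  xy <- grid_minimum(w$ax, t(sm))
  fovea_center(xy[1L], xy[2L], "smooth_min")
}

#' Locate the foveal centre by a named strategy
#'
#' Dispatcher over the four localization strategies.
#'
#' @param cloud A [trt_cloud()].
#' @param method One of `"none"`, `"min"`, `"interp_min"`,
#'   `"smooth_min"`.
#' @param ... Passed to the strategy (e.g. `region_radius_mm`,
#'   `window_mm`, `spacing_mm`, `kernel_radius_mm`).
#' @return A [fovea_center()] tagged with `method`.
#' @export
locate_center <- function(cloud, method, ...) {
  if (!is.character(method) || length(method) != 1L ||
      !method %in% c("none", "min", "interp_min", "smooth_min"))
    stop("unknown foveal center location method: ",
         paste(method, collapse = ", "), call. = FALSE)
  switch(method,
         none = locate_none(cloud),
         min = locate_min(cloud, ...),
         interp_min = locate_interp_min(cloud, ...),
         smooth_min = locate_smooth_min(cloud, ...))
}
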