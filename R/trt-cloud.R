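#' Scattered total retinal thickness point cloud
#'
#' One TRT value per A-scan at its lateral position.  Clouds derived from
#' a scan keep the acquisition metadata and the B-scan/A-scan indices,
#' which later allow an exact structured triangulation of the sampling
#' lattice; hand-built clouds without metadata fall back to a generic
#' Delaunay triangulation when resampled.
#'
#' @param x_mm,y_mm,trt_um Numeric vectors of equal length.
#' @param bscan_index,ascan_index Optional 0-based acquisition indices.
#' @param meta Optional [scan_meta()].
#' @return An object of class `trt_cloud` (a data frame).
#' @export
trt_cloud <- function(x_mm, y_mm, trt_um,
                      bscan_index = NULL, ascan_index = NULL, meta = NULL) {
  n <- length(x_mm)
  stopifnot(length(y_mm) == n, length(trt_um) == n)
  if (!all(is.finite(x_mm)) || !all(is.finite(y_mm)))
    stop("cloud coordinates must be finite", call. = FALSE)
  bad <- which(!is.finite(trt_um) | trt_um <= 0)
  if (length(bad))
    stop(sprintf("non-positive or non-finite TRT at point(s) %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  d <- data.frame(x_mm = x_mm, y_mm = y_mm, trt_um = trt_um)
  if (!is.null(bscan_index)) d$bscan_index <- as.integer(bscan_index)
  if (!is.null(ascan_index)) d$ascan_index <- as.integer(ascan_index)
  structure(d, meta = meta, class = c("trt_cloud", "data.frame"))
}

#' Compute total retinal thickness from layer segmentations
#'
#' TRT is the pointwise height difference between the inner limiting
#' membrane and Bruch's membrane, `TRT = ILM - BM`.  With BM used as the
#' flat reference this removes the eye curvature from the map.  A
#' non-positive thickness anywhere signals a segmentation failure and is
#' reported as an error, never silently dropped.
#'
#' @param scan An [oct_scan()].
#' @return A [trt_cloud()] carrying the scan metadata.
#' @export
compute_trt <- function(scan) {
  stopifnot(inherits(scan, "oct_scan"))
  d <- scan$data
  trt <- d$ilm_um - d$bm_um
  bad <- which(trt <= 0)
  if (length(bad))
    stop(sprintf(
      "non-positive TRT at A-scan row(s) %s (B-scan %s): segmentation failure",
      paste(head(bad, 5L), collapse = ", "),
      paste(head(d$bscan_index[bad], 5L), collapse = ", ")), call. = FALSE)
  trt_cloud(d$x_mm, d$y_mm, trt,
            bscan_index = d$bscan_index, ascan_index = d$ascan_index,
            meta = scan$meta)
}

#' Standardize the lateral orientation of a cloud
#'
#' Left eyes (OS) are mirrored about the vertical axis so that, as for
#' right eyes (OD), positive x points from temporal to nasal retina.
#' Applying the operation twice to an OS cloud restores the original.
#'
#' @param cloud A [trt_cloud()].
#' @param eye `"OD"` (returned unchanged) or `"OS"` (x negated).
#' @return The standardized [trt_cloud()].
#' @export
standardize_orientation <- function(cloud, eye) {
  stopifnot(inherits(cloud, "trt_cloud"))
  if (!is.character(eye) || length(eye) != 1L || !eye %in% c("OD", "OS"))
    stop("eye must be \"OD\" or \"OS\"", call. = FALSE)
  if (eye == "OS") cloud$x_mm <- -cloud$x_mm
  cloud
}

#' Translate a cloud so the foveal center sits at the origin
#'
#' @param cloud A [trt_cloud()].
#' @param center A [fovea_center()] or numeric `c(x, y)` in mm.
#' @return The recentered [trt_cloud()].
#' @export
recenter <- function(cloud, center) {
  stopifnot(inherits(cloud, "trt_cloud"))
  ctr <- as_center_xy(center)
  cloud$x_mm <- cloud$x_mm - ctr[1L]
  cloud$y_mm <- cloud$y_mm - ctr[2L]
  cloud
}

as_center_xy <- function(center) {
  if (inherits(center, "fovea_center")) center <- c(center$x_mm, center$y_mm)
  center <- as.numeric(center)
  if (length(center) != 2L || !all(is.finite(center)))
    stop("center must be two finite coordinates", call. = FALSE)
  center
}
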