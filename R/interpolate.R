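# Scattered-data interpolation layer.
#
# Clouds that come from an acquisition keep their lattice indices, so the
# triangulation of the sampling pattern is built exactly (raster rows ->
# split quads; star diameters -> radial strips around a central fan).
# Generic clouds are triangulated with deldir, escalating a deterministic
# coordinate jitter when the point set is degenerate (exact lattices).
# In both cases the interpolant itself is the C1 Clough-Tocher cubic
# implemented in src/clough_tocher.cpp, evaluated on the true coordinates.

triangulate_lattice <- function(nx, ny) {
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  a <- id(i, j); b <- id(i + 1L, j); cc <- id(i + 1L, j + 1L); d <- id(i, j + 1L)
  rbind(cbind(a, b, cc), cbind(a, cc, d))
}

triangulate_raster <- function(d) {
  ord <- order(d$bscan_index, d$ascan_index)
  nb <- length(unique(d$bscan_index))
  na <- nrow(d) / nb
  if (na != round(na)) stop("raster cloud is not a complete lattice", call. = FALSE)
  tri <- triangulate_lattice(as.integer(na), as.integer(nb))
  matrix(ord[tri], ncol = 3L)
}

# Star pattern: each B-scan is a diameter through the scan centre.  Split
# every diameter at the crossing point into two rays, strip-triangulate
# consecutive rays in angular order and close the centre with a fan over
# the innermost ring.
triangulate_star <- function(d) {
  ctr <- c(mean(d$x_mm), mean(d$y_mm))
  rays <- list()
  for (b in sort(unique(d$bscan_index))) {
    idx <- which(d$bscan_index == b)
    idx <- idx[order(d$ascan_index[idx])]
    vx <- d$x_mm[idx] - ctr[1L]; vy <- d$y_mm[idx] - ctr[2L]
    ux <- vx[length(vx)] - vx[1L]; uy <- vy[length(vy)] - vy[1L]
    nrm <- sqrt(ux^2 + uy^2)
    ux <- ux / nrm; uy <- uy / nrm
    s <- vx * ux + vy * uy
    pos <- idx[s > 0][order(s[s > 0])]
    neg <- idx[s < 0][order(-s[s < 0])]
    if (length(pos) < 2L || length(neg) < 2L)
      stop("star B-scan does not straddle the scan centre", call. = FALSE)
    rays[[length(rays) + 1L]] <- list(idx = pos, ang = atan2(uy, ux))
    rays[[length(rays) + 1L]] <- list(idx = neg, ang = atan2(-uy, -ux))
  }
  angs <- vapply(rays, `[[`, numeric(1L), "ang") %% (2 * pi)
  rays <- rays[order(angs)]
  m <- length(rays)
  tris <- vector("list", m + 1L)
  rad <- function(i) sqrt((d$x_mm[i] - ctr[1L])^2 + (d$y_mm[i] - ctr[2L])^2)
  for (k in seq_len(m)) {
    a <- rays[[k]]$idx; b <- rays[[if (k == m) 1L else k + 1L]]$idx
    ra <- rad(a); rb <- rad(b)
    out <- matrix(0L, length(a) + length(b) - 2L, 3L)
    ia <- 1L; ib <- 1L; nt <- 0L
    while (ia < length(a) || ib < length(b)) {
      adv_a <- ib >= length(b) ||
        (ia < length(a) && ra[ia + 1L] <= rb[ib + 1L])
      nt <- nt + 1L
      if (adv_a) {
        out[nt, ] <- c(a[ia], b[ib], a[ia + 1L]); ia <- ia + 1L
      } else {
        out[nt, ] <- c(a[ia], b[ib], b[ib + 1L]); ib <- ib + 1L
      }
    }
    tris[[k]] <- out[seq_len(nt), , drop = FALSE]
  }
  inner <- vapply(rays, function(r) r$idx[1L], integer(1L))
  if (m >= 3L)
    tris[[m + 1L]] <- cbind(inner[1L], inner[2:(m - 1L)], inner[3:m])
  do.call(rbind, tris)
}

triangulate_generic <- function(x, y) {
  if (length(x) < 3L) stop("need at least 3 points to triangulate", call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  # collinearity: Gram determinant of the centred coordinates
  area2 <- sum(xc^2) * sum(yc^2) - sum(xc * yc)^2
  if (area2 <= 1e-20 * (sum(xc^2) + sum(yc^2))^2)
    stop("degenerate geometry: points are collinear", call. = FALSE)
  scale <- max(diff(range(x)), diff(range(y)))
  n <- length(x)
  phase <- sin(seq_len(n) * 12.9898) * 43758.5453
  jit <- (phase - floor(phase)) - 0.5   # deterministic in [-0.5, 0.5)
  for (eps in c(0, scale * c(1e-9, 1e-7, 1e-5, 1e-4))) {
    tm <- tryCatch({
      dd <- deldir::deldir(x + eps * jit, y + eps * rev(jit))
      deldir::triMat(dd)
    }, error = function(e) NULL)
    if (!is.null(tm)) return(unname(as.matrix(tm)))
  }
  stop("triangulation failed for this cloud", call. = FALSE)
}

cloud_triangulation <- function(cloud) {
  meta <- attr(cloud, "meta")
  has_idx <- all(c("bscan_index", "ascan_index") %in% names(cloud))
  if (!is.null(meta) && has_idx) {
    if (meta$pattern == "raster") return(triangulate_raster(cloud))
    if (meta$pattern == "star") return(triangulate_star(cloud))
  }
  triangulate_generic(cloud$x_mm, cloud$y_mm)
}

cloud_interpolant <- function(cloud) {
  stopifnot(inherits(cloud, "trt_cloud"))
  tri <- cloud_triangulation(cloud)
  grad <- ct_gradients(cloud$x_mm, cloud$y_mm, cloud$trt_um, tri)
  structure(list(x = cloud$x_mm, y = cloud$y_mm, z = cloud$trt_um,
                 tri = tri, grad = grad), class = "ct_interp")
}

interp_at <- function(itp, qx, qy) {
  ct_evaluate(itp$x, itp$y, itp$z, itp$tri, itp$grad,
              as.numeric(qx), as.numeric(qy))
}

#' Interpolate a TRT cloud at arbitrary lateral positions
#'
#' Triangulation-based C1 piecewise-cubic (Clough-Tocher) interpolation
#' of the scattered thickness samples.  Queries outside the convex hull
#' of the cloud return `NA` (no extrapolation).
#'
#' @param cloud A [trt_cloud()].
#' @param x_mm,y_mm Query coordinates (mm), recycled to a common length.
#' @return Numeric vector of interpolated thicknesses (um).
#' @export
interpolate_cloud <- function(cloud, x_mm, y_mm) {
  n <- max(length(x_mm), length(y_mm))
  interp_at(cloud_interpolant(cloud), rep_len(x_mm, n), rep_len(y_mm, n))
}
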