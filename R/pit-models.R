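# Parametric foveal pit models and the shared nonlinear least-squares
# fitting engine.
#
# The six model families are reconstructions of the cited originals: the
# source publications are paraphrased by family, modelled region and
# coefficient count, and the exact equations used here are therefore
# documented reconstructions honouring those constraints (see the
# vignette), not numerical replicas of the original implementations.
#
# "B-scan" models are fitted per diametric profile: radial direction k
# is joined with direction k + n/2 (mirrored radii) to form a two-sided
# profile, preserving each model's two-sided shape assumptions.

model_registry <- list(
  dubis   = list(family = "difference of two Gaussians", region = "bscan",
                 n_params = 6L, fixes_center = FALSE, fixes_rim = FALSE),
  ding    = list(family = "polynomial surface and Gaussian", region = "trt_map",
                 n_params = 8L, fixes_center = FALSE, fixes_rim = FALSE),
  scheibe = list(family = "second derivative of a Gaussian", region = "radial",
                 n_params = 4L, fixes_center = TRUE, fixes_rim = FALSE),
  liu     = list(family = "sloped piecemeal Gaussian", region = "bscan",
                 n_params = 6L, fixes_center = FALSE, fixes_rim = FALSE),
  yadav   = list(family = "cubic Bezier curves", region = "center_rim",
                 n_params = 5L, fixes_center = TRUE, fixes_rim = TRUE),
  breher  = list(family = "sum of three Gaussians", region = "bscan",
                 n_params = 9L, fixes_center = FALSE, fixes_rim = FALSE),
  loess   = list(family = "local quadratic regression smoother", region = "bscan",
                 n_params = 0L, fixes_center = FALSE, fixes_rim = FALSE),
  movavg  = list(family = "moving average smoother", region = "bscan",
                 n_params = 0L, fixes_center = FALSE, fixes_rim = FALSE)
)

#' Describe a foveal pit model or smoother
#'
#' @param model_id One of `"dubis"`, `"ding"`, `"scheibe"`, `"liu"`,
#'   `"yadav"`, `"breher"`, `"loess"`, `"movavg"`.
#' @param span For `"loess"`: span fraction in `[0.01, 0.50]`.
#' @param window For `"movavg"`: window length in `[5, 60]` samples.
#' @return An object of class `model_spec` with the family description,
#'   modelled region, coefficient count, and fixed-point flags.
#' @export
model_spec <- function(model_id, span = 0.20, window = 15L) {
  if (!is.character(model_id) || length(model_id) != 1L ||
      !model_id %in% names(model_registry))
    stop("unknown model id: ", paste(model_id, collapse = ", "), call. = FALSE)
  entry <- model_registry[[model_id]]
  params <- list()
  if (model_id == "loess") params$span <- span
  if (model_id == "movavg") params$window <- as.integer(window)
  structure(c(list(model_id = model_id), entry, list(params = params)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %s (%s region, %d parameter(s))\n",
              x$model_id, x$family, x$region, x$n_params))
  invisible(x)
}

# ---- model functions ------------------------------------------------------

model_fun_dubis <- function(par, x) {
  par[1L] + par[3L] * exp(-(x - par[2L])^2 / (2 * par[4L]^2)) -
    par[5L] * exp(-(x - par[2L])^2 / (2 * par[6L]^2))
}

model_fun_ding <- function(par, xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  par[1L] + par[2L] * x + par[3L] * y + par[4L] * x^2 + par[5L] * y^2 -
    par[6L] * exp(-(x^2 / (2 * par[7L]^2) + y^2 / (2 * par[8L]^2)))
}

model_fun_scheibe <- function(par, r) {
  u <- par[1L] * r^par[3L]
  par[1L] * par[2L]^2 * r^par[3L] * exp(-u) + par[4L] * (1 - exp(-u))
}

model_fun_liu <- function(par, x) {
  dx <- x - par[2L]
  wall <- pmax(abs(dx) - par[3L], 0)
  par[1L] + par[4L] * dx + par[5L] * (1 - exp(-wall^2 / (2 * par[6L]^2)))
}

model_fun_breher <- function(par, x) {
  par[1L] * exp(-(x - par[2L])^2 / (2 * par[3L]^2)) +
    par[4L] * exp(-(x - par[5L])^2 / (2 * par[6L]^2)) +
    par[7L] * exp(-(x - par[8L])^2 / (2 * par[9L]^2))
}

bernstein3 <- function(t) {
  cbind((1 - t)^3, 3 * t * (1 - t)^2, 3 * t^2 * (1 - t), t^3)
}

# Two pinned cubic Bezier segments per direction.  With the control
# abscissae fixed at the thirds of each segment the curve is a cubic
# polynomial in the normalized radius, so the free ordinates solve by
# linear least squares.  Anchors (centre value, rim value, rim radius)
# are data, not coefficients.
model_fun_yadav <- function(par, r, anchors) {
  t0 <- anchors$center_um; trim <- anchors$rim_um; rr <- anchors$rim_radius_mm
  rmax <- anchors$radius_max_mm
  out <- numeric(length(r))
  inner <- r <= rr
  ti <- r[inner] / rr
  out[inner] <- bernstein3(ti) %*% c(t0, par[1L], par[2L], trim)
  if (any(!inner)) {
    to <- (r[!inner] - rr) / (rmax - rr)
    out[!inner] <- bernstein3(to) %*% c(trim, par[3L], par[4L], par[5L])
  }
  out
}

#' Evaluate a pit model at given coordinates
#'
#' Deterministic evaluation of a fitted (or hand-specified) model
#' function.  For B-scan models (`dubis`, `liu`, `breher`) `coords` is
#' the signed lateral position of a diametric profile; for `scheibe` it
#' is the radius and the returned value is the rise above the centre
#' (zero at the origin by construction); for `ding` a two-column matrix
#' of (x, y); for `yadav` the radius, with the pinned anchors supplied
#' via `anchors`.
#'
#' @param spec A [model_spec()].
#' @param coefficients Coefficient vector of length `spec$n_params`.
#' @param coords Evaluation coordinates (see Details).
#' @param anchors For `yadav` only: `list(center_um, rim_um,
#'   rim_radius_mm, radius_max_mm)`.
#' @return Numeric vector of model values.
#' @export
evaluate_model <- function(spec, coefficients, coords, anchors = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(coefficients) != spec$n_params)
    stop(sprintf("%s expects %d coefficients, got %d", spec$model_id,
                 spec$n_params, length(coefficients)), call. = FALSE)
  switch(spec$model_id,
         dubis = model_fun_dubis(coefficients, coords),
         ding = model_fun_ding(coefficients, as.matrix(coords)),
         scheibe = model_fun_scheibe(coefficients, coords),
         liu = model_fun_liu(coefficients, coords),
         breher = model_fun_breher(coefficients, coords),
         yadav = {
           if (is.null(anchors))
             stop("yadav evaluation requires the pinned anchors", call. = FALSE)
           model_fun_yadav(coefficients, coords, anchors)
         },
         stop("model ", spec$model_id, " has no closed-form evaluation",
              call. = FALSE))
}

# ---- fitting engine -------------------------------------------------------

# deterministic restart schedule: multiplicative perturbations applied to
# scale-like (widths) and amplitude-like coefficients
restart_schedule <- list(c(1, 1), c(0.5, 1), c(2, 1), c(1, 0.6),
                         c(0.7, 1.5), c(1.6, 0.7))

lm_fit_unit <- function(resid_fn, par0, lower, upper, scale_mask, amp_mask) {
  best <- NULL
  for (sched in restart_schedule) {
    par <- par0
    par[scale_mask] <- par[scale_mask] * sched[1L]
    par[amp_mask] <- par[amp_mask] * sched[2L]
    par <- pmin(pmax(par, lower), upper)
    res <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = par, fn = resid_fn, lower = lower,
                           upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 1000L, ftol = 1e-6, ptol = 1e-6,
                             maxfev = 100000L))),
      error = function(e) NULL)
    if (is.null(res)) next
    conv <- res$info %in% c(1L, 2L, 3L, 4L)
    cand <- list(par = res$par, deviance = res$deviance, converged = conv,
                 niter = res$niter)
    if (is.null(best) || cand$deviance < best$deviance) best <- cand
    if (conv && best$deviance <= res$deviance * (1 + 1e-9) && best$converged)
      break
  }
  if (is.null(best))
    best <- list(par = par0, deviance = Inf, converged = FALSE, niter = 0L)
  best
}

diametric_profiles <- function(profiles) {
  nd <- length(profiles$angles_rad)
  if (nd %% 2L != 0L)
    stop("diametric pairing needs an even number of directions", call. = FALSE)
  half <- nd / 2L
  r <- profiles$radii_mm
  x <- c(-rev(r[-1L]), r)
  lapply(seq_len(half), function(k) {
    v <- c(rev(profiles$values_um[k + half, -1L]), profiles$values_um[k, ])
    list(k_pos = k, k_neg = k + half, x = x, y = v)
  })
}

edge_level <- function(x, y) mean(y[abs(x) >= 0.9 * max(abs(x))])

init_dubis <- function(x, y) {
  z0 <- edge_level(x, y)
  ctr <- y[which.min(abs(x))]
  c(z0, 0, max(y) - z0 + 10, 1.0, max(max(y) - ctr, 5), 0.35)
}

init_liu <- function(x, y) {
  i0 <- which.min(y)
  c(min(y), x[i0], 0.1, 0, max(y) - min(y), 0.4)
}

init_breher <- function(x, y) {
  # wide base Gaussian carrying the perifoveal level, a negative central
  # Gaussian digging the pit, and a broad mound lifting the rim region
  edge <- edge_level(x, y)
  ctr <- y[which.min(abs(x))]
  c(edge, 0, 5, ctr - max(y), 0, 0.35, max(y) - edge, 0, 1.2)
}

init_scheibe <- function(r, d) {
  # d = rise above centre
  i_max <- which.max(d)
  R0 <- max(r[i_max], 0.25)
  c(2 / R0^2, sqrt(max(max(d), 1)), 2, max(d[length(d)], 1))
}

init_ding <- function(xy, z) {
  edge <- mean(z[rowSums(xy^2) >= 0.9 * max(rowSums(xy^2))])
  ctr <- mean(z[rowSums(xy^2) <= 1e-9])
  c(edge, 0, 0, 0, 0, max(edge - ctr, 5), 0.35, 0.35)
}

canonicalize <- function(model_id, par) {
  if (model_id == "dubis" && par[4L] < par[6L]) {
    par <- c(par[1L], par[2L], -par[5L], par[6L], -par[3L], par[4L])
  }
  if (model_id == "breher") {
    comp <- matrix(par, nrow = 3L, byrow = TRUE)
    comp <- comp[order(-comp[, 3L]), , drop = FALSE]
    par <- as.vector(t(comp))
  }
  par
}

fit_bscan_model <- function(profiles, spec, init) {
  dp <- diametric_profiles(profiles)
  p <- spec$n_params
  fun <- switch(spec$model_id, dubis = model_fun_dubis,
                liu = model_fun_liu, breher = model_fun_breher)
  init_fn <- switch(spec$model_id, dubis = init_dubis,
                    liu = init_liu, breher = init_breher)
  lower <- switch(spec$model_id,
                  dubis = c(-Inf, -Inf, -Inf, 1e-6, -Inf, 1e-6),
                  liu = c(-Inf, -Inf, 1e-6, -Inf, -Inf, 1e-6),
                  breher = rep(c(-Inf, -Inf, 1e-6), 3L))
  scale_mask <- switch(spec$model_id,
                       dubis = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
                       liu = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
                       breher = rep(c(FALSE, FALSE, TRUE), 3L))
  amp_mask <- switch(spec$model_id,
                     dubis = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
                     liu = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
                     breher = rep(c(TRUE, FALSE, FALSE), 3L))
  coefs <- matrix(NA_real_, length(dp), p)
  fitted <- profiles$values_um * NA_real_
  conv <- logical(length(dp)); nit <- integer(length(dp))
  for (u in seq_along(dp)) {
    x <- dp[[u]]$x; y <- dp[[u]]$y
    fit_x <- x; fit_y <- y
    if (spec$model_id == "liu") {
      # pit-only fitting region: between the two detected rims
      i_neg <- which.max(y[x < 0]); i_pos <- which.max(y[x > 0])
      xl <- x[x < 0][i_neg]; xr <- x[x > 0][i_pos]
      keep <- x >= xl & x <= xr
      fit_x <- x[keep]; fit_y <- y[keep]
    }
    par0 <- if (is.null(init)) init_fn(x, y) else init
    res <- lm_fit_unit(function(pp) fun(pp, fit_x) - fit_y, par0,
                       lower, rep(Inf, p), scale_mask, amp_mask)
    coefs[u, ] <- canonicalize(spec$model_id, res$par)
    conv[u] <- res$converged; nit[u] <- res$niter
    pred <- fun(res$par, x)
    nr <- length(profiles$radii_mm)
    fitted[dp[[u]]$k_pos, ] <- pred[(nr):(2L * nr - 1L)]
    fitted[dp[[u]]$k_neg, ] <- rev(pred[1L:nr])
  }
  list(coefficients = coefs, fitted = fitted, converged = conv, niter = nit)
}

fit_scheibe <- function(profiles, init) {
  r <- profiles$radii_mm
  nd <- length(profiles$angles_rad)
  coefs <- matrix(NA_real_, nd, 4L)
  fitted <- profiles$values_um * NA_real_
  conv <- logical(nd); nit <- integer(nd)
  lower <- c(1e-6, 1e-6, 1e-6, -Inf)
  for (k in seq_len(nd)) {
    y <- profiles$values_um[k, ]
    d <- y - y[1L]
    par0 <- if (is.null(init)) init_scheibe(r, d) else init
    res <- lm_fit_unit(function(pp) model_fun_scheibe(pp, r) - d, par0,
                       lower, rep(Inf, 4L),
                       scale_mask = c(TRUE, TRUE, FALSE, FALSE),
                       amp_mask = c(FALSE, FALSE, FALSE, TRUE))
    coefs[k, ] <- res$par
    conv[k] <- res$converged; nit[k] <- res$niter
    fitted[k, ] <- y[1L] + model_fun_scheibe(res$par, r)
  }
  list(coefficients = coefs, fitted = fitted, converged = conv, niter = nit)
}

fit_ding <- function(profiles, init) {
  r <- profiles$radii_mm; a <- profiles$angles_rad
  xy <- cbind(as.vector(outer(a, r, function(a, r) r * cos(a))),
              as.vector(outer(a, r, function(a, r) r * sin(a))))
  z <- as.vector(profiles$values_um)
  par0 <- if (is.null(init)) init_ding(xy, z) else init
  lower <- c(rep(-Inf, 6L), 1e-6, 1e-6)
  res <- lm_fit_unit(function(pp) model_fun_ding(pp, xy) - z, par0,
                     lower, rep(Inf, 8L),
                     scale_mask = c(rep(FALSE, 6L), TRUE, TRUE),
                     amp_mask = c(rep(FALSE, 5L), TRUE, FALSE, FALSE))
  fitted <- matrix(model_fun_ding(res$par, xy), nrow = length(a))
  list(coefficients = matrix(res$par, 1L), fitted = fitted,
       converged = res$converged, niter = res$niter)
}

fit_yadav <- function(profiles) {
  r <- profiles$radii_mm
  nd <- length(profiles$angles_rad)
  nr <- length(r)
  coefs <- matrix(NA_real_, nd, 5L)
  fitted <- profiles$values_um * NA_real_
  anchors <- vector("list", nd)
  for (k in seq_len(nd)) {
    y <- profiles$values_um[k, ]
    # the rim anchor index is detected on a lightly smoothed profile so a
    # single noisy sample cannot become the pinned landmark; the pinned
    # values themselves stay the raw samples
    i_rim <- which.max(smooth_movavg(y, 5L)[-1L]) + 1L
    anc <- list(center_um = y[1L], rim_um = y[i_rim],
                rim_radius_mm = r[i_rim], radius_max_mm = r[nr])
    # inner segment: endpoints pinned, solve 2 free ordinates linearly
    ti <- r[1:i_rim] / r[i_rim]
    Bi <- bernstein3(ti)
    rhs_i <- y[1:i_rim] - Bi[, 1L] * anc$center_um - Bi[, 4L] * anc$rim_um
    ci <- stats::lm.fit(Bi[, 2:3, drop = FALSE], rhs_i)$coefficients
    if (i_rim < nr) {
      to <- (r[(i_rim):nr] - r[i_rim]) / (r[nr] - r[i_rim])
      Bo <- bernstein3(to)
      rhs_o <- y[(i_rim):nr] - Bo[, 1L] * anc$rim_um
      co <- stats::lm.fit(Bo[, 2:4, drop = FALSE], rhs_o)$coefficients
    } else {
      co <- rep(anc$rim_um, 3L)
    }
    par <- c(ci, co)
    coefs[k, ] <- par
    anchors[[k]] <- anc
    fitted[k, ] <- model_fun_yadav(par, r, anc)
    # exact fixed points by construction (guard against round-off)
    fitted[k, 1L] <- y[1L]
    fitted[k, i_rim] <- y[i_rim]
  }
  list(coefficients = coefs, fitted = fitted,
       converged = rep(TRUE, nd), niter = rep(1L, nd), anchors = anchors)
}

fit_smoother <- function(profiles, spec) {
  dp <- diametric_profiles(profiles)
  fitted <- profiles$values_um * NA_real_
  nr <- length(profiles$radii_mm)
  for (u in seq_along(dp)) {
    sm <- if (spec$model_id == "loess")
      smooth_loess(dp[[u]]$y, span_fraction = spec$params$span)
    else
      smooth_movavg(dp[[u]]$y, window = spec$params$window)
    fitted[dp[[u]]$k_pos, ] <- sm[(nr):(2L * nr - 1L)]
    fitted[dp[[u]]$k_neg, ] <- rev(sm[1L:nr])
  }
  list(coefficients = matrix(numeric(0L), length(dp), 0L), fitted = fitted,
       converged = rep(TRUE, length(dp)), niter = rep(0L, length(dp)))
}

#' Fit a foveal pit model or smoother to radial profiles
#'
#' Minimizes squared residuals per fitted unit with the
#' Levenberg-Marquardt algorithm (at most 1000 iterations, residual and
#' coefficient tolerances of 1e-6), using data-driven default initial
#' coefficients and a deterministic schedule of up to 5 perturbed
#' restarts on non-convergence, keeping the lowest-error solution.  The
#' fitted unit depends on the modelled region: per diametric profile for
#' B-scan models (`dubis`, `liu`, `breher` and the two smoothers), per
#' direction for `scheibe` and `yadav`, and a single whole-map fit for
#' `ding`.
#'
#' @param profiles A complete [radial_profiles()] (no undefined samples).
#' @param spec A [model_spec()].
#' @param init Optional initial coefficient vector overriding the
#'   data-driven defaults (parametric models only).
#' @return An object of class `pit_fit`: coefficients (one row per
#'   fitted unit), fitted values on the input sampling, overall RMSE,
#'   convergence flags and iteration counts.
#' @export
fit_model <- function(profiles, spec, init = NULL) {
  stopifnot(inherits(profiles, "radial_profiles"))
  if (!inherits(spec, "model_spec")) stop("spec must be a model_spec", call. = FALSE)
  if (anyNA(profiles$values_um))
    stop("profiles contain undefined samples; complete them before fitting",
         call. = FALSE)
  if (!is.null(init) && length(init) != spec$n_params)
    stop("init must have length ", spec$n_params, call. = FALSE)
  res <- switch(spec$model_id,
                dubis = , liu = , breher = fit_bscan_model(profiles, spec, init),
                scheibe = fit_scheibe(profiles, init),
                ding = fit_ding(profiles, init),
                yadav = fit_yadav(profiles),
                loess = , movavg = fit_smoother(profiles, spec))
  rmse <- sqrt(mean((res$fitted - profiles$values_um)^2))
  structure(list(model_id = spec$model_id, spec = spec,
                 coefficients = res$coefficients,
                 fitted_values_um = res$fitted,
                 rmse_um = rmse,
                 converged = all(res$converged),
                 unit_converged = res$converged,
                 n_iterations = max(res$niter),
                 anchors = res$anchors,
                 profiles = profiles),
            class = "pit_fit")
}

#' @export
print.pit_fit <- function(x, ...) {
  cat(sprintf("<pit_fit> %s: rmse %.3f um, %sconverged (max %d iterations)\n",
              x$model_id, x$rmse_um, if (x$converged) "" else "NOT ",
              x$n_iterations))
  invisible(x)
}
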