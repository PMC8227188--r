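# Synthetic foveal surfaces and OCT acquisitions.
#
# The ground-truth thickness surface is built from a radial pit profile
# of the second-derivative-of-a-Gaussian family: the rise above the
# centre along radius r is
#
#   D(r) = mu * sigma^2 * r^gamma * exp(-mu r^gamma)
#        + alpha * (1 - exp(-mu r^gamma)),
#
# which is zero at the centre, climbs to a rim bump at mu r^gamma =
# 1 + alpha/sigma^2 and settles towards the perifoveal level alpha.
# (mu, sigma) are solved so the pit reproduces requested CFT, rim height
# and rim radius; low-order harmonic modulation of mu and alpha in the
# polar angle creates the nasal/temporal asymmetry of real foveas.

solve_pit_coefficients <- function(depth_um, rim_radius_mm, gamma,
                                   alpha_um) {
  stopifnot(depth_um > 0, rim_radius_mm > 0, gamma > 0,
            alpha_um > 0, alpha_um < depth_um)
  peak <- function(sigma2) {
    ustar <- 1 + alpha_um / sigma2
    sigma2 * ustar * exp(-ustar) + alpha_um * (1 - exp(-ustar)) - depth_um
  }
  sigma2 <- stats::uniroot(peak, c(1e-8, 1e8), tol = 1e-12)$root
  ustar <- 1 + alpha_um / sigma2
  mu <- ustar / rim_radius_mm^gamma
  list(mu = mu, sigma2 = sigma2, gamma = gamma, alpha = alpha_um)
}

#' Build a ground-truth foveal thickness surface
#'
#' Constructs a smooth, radially unimodal pit surface T(x, y) with known
#' geometry.  `shape_params` controls the pit: `cft_um` (default 225),
#' `rim_height_um` (340), `rim_radius_mm` (1.0), `gamma` (radial
#' exponent, 2), `alpha_frac` (perifoveal level as a fraction of pit
#' depth, 0.8), `center` (pit position in surface coordinates, c(0, 0)),
#' and `modulation` (harmonic amplitudes `mu_cos`, `mu_sin`, `mu_cos2`,
#' `alpha_cos`; when omitted they are drawn from N(0, 0.05) under
#' `seed`).  These defaults are synthetic conventions chosen to be
#' order-of-magnitude realistic for healthy adult foveas, not values
#' taken from any specific cohort.
#'
#' True per-direction parameters (CFT, rim height, rim radius, maximum
#' slope for 24 directions) are computed from the analytic surface on a
#' dense 0.0005 mm radial lattice.
#'
#' @param shape_params Named list overriding the defaults above.
#' @param seed Integer seed for the random modulation draw.
#' @return An object of class `surface_truth`: the evaluable thickness
#'   function, the true centre, the resolved coefficients and the true
#'   per-direction parameters.
#' @export
make_surface <- function(shape_params = list(), seed = 1L) {
  p <- utils::modifyList(list(cft_um = 225, rim_height_um = 340,
                              rim_radius_mm = 1.0, gamma = 2,
                              alpha_frac = 0.8, center = c(0, 0),
                              modulation = NULL), shape_params)
  depth <- p$rim_height_um - p$cft_um
  if (depth <= 0)
    stop("rim_height_um must exceed cft_um: no pit", call. = FALSE)
  if (p$alpha_frac <= 0 || p$alpha_frac >= 1)
    stop("alpha_frac must lie in (0, 1)", call. = FALSE)
  if (is.null(p$modulation)) {
    m <- local_seed(seed, rnorm(4L, 0, 0.05))
    p$modulation <- list(mu_cos = m[1L], mu_sin = m[2L], mu_cos2 = m[3L],
                         alpha_cos = m[4L])
  }
  mod <- p$modulation
  if (max(abs(unlist(mod))) >= 0.5)
    stop("modulation amplitudes must stay below 0.5", call. = FALSE)
  base <- solve_pit_coefficients(depth, p$rim_radius_mm, p$gamma,
                                 p$alpha_frac * depth)
  ctr <- p$center
  fn <- function(x, y) {
    dx <- x - ctr[1L]; dy <- y - ctr[2L]
    r <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    mu <- base$mu * (1 + mod$mu_cos * cos(th) + mod$mu_sin * sin(th) +
                       mod$mu_cos2 * cos(2 * th))
    alpha <- base$alpha * (1 + mod$alpha_cos * cos(th))
    u <- mu * r^base$gamma
    p$cft_um + base$sigma2 * mu * r^base$gamma * exp(-u) +
      alpha * (1 - exp(-u))
  }
  truth <- structure(list(fn = fn, true_center = ctr, shape = p,
                          coefficients = base, seed = seed),
                     class = "surface_truth")
  truth$true_params <- true_surface_params(truth)
  # pit sanity: the centre must be an interior minimum
  if (any(truth$true_params$rim_height_um <= p$cft_um) ||
      any(truth$true_params$rim_radius_mm <= 0.05))
    stop("shape parameters produce a non-pit surface", call. = FALSE)
  truth
}

true_surface_params <- function(truth, n_directions = 24L,
                                radius_mm = 2.0, step_mm = 5e-4) {
  r <- seq(0, radius_mm, by = step_mm)
  ang <- 2 * pi * (seq_len(n_directions) - 1L) / n_directions
  v <- t(vapply(ang, function(a) {
    truth$fn(truth$true_center[1L] + r * cos(a),
             truth$true_center[2L] + r * sin(a))
  }, numeric(length(r))))
  suppressWarnings(params_from_values(v, r, "truth"))
}

#' @export
print.surface_truth <- function(x, ...) {
  tp <- x$true_params
  cat(sprintf(
    "<surface_truth> centre (%.3f, %.3f) mm; CFT %.1f um, rim %.1f um at %.3f mm, max slope %.1f um/mm\n",
    x$true_center[1L], x$true_center[2L], tp$cft_um, tp$mean_rim_height_um,
    tp$mean_rim_radius_mm, tp$mean_max_slope_um_mm))
  invisible(x)
}

#' Acquisition settings for a synthetic scan
#'
#' Geometry defaults emulate a Spectralis macular protocol with a
#' 0.3 mm/degree schematic-eye conversion: raster scans cover 30 x 25
#' degrees (9.0 x 7.5 mm) with 25 B-scans of 512 A-scans; star scans
#' cover a 15-degree (4.5 mm) diameter with 12 diametric B-scans of 768
#' A-scans.
#'
#' @param pattern `"raster"` or `"star"`.
#' @param decenter_mm Fixation error `c(dx, dy)`: the pit appears at
#'   this offset from the scan centre.
#' @param noise_sd_um Standard deviation of the correlated measurement/
#'   segmentation noise (um).
#' @param noise_correlation_mm Correlation length of the noise along
#'   each B-scan (mm).
#' @param blip_rate Expected fraction of A-scans affected by
#'   segmentation blips (short runs of displaced boundary, about 5
#'   samples long).
#' @param blip_amplitude_um Blip magnitude (um, random sign).
#' @param seed Integer seed for the noise draw.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(pattern = c("raster", "star"),
                               decenter_mm = c(0, 0),
                               noise_sd_um = 2.5,
                               noise_correlation_mm = 0.15,
                               blip_rate = 0.001,
                               blip_amplitude_um = 25,
                               seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(length(decenter_mm) == 2L, all(is.finite(decenter_mm)),
            noise_sd_um >= 0, noise_correlation_mm > 0,
            blip_rate >= 0, blip_rate <= 1, blip_amplitude_um >= 0)
  structure(list(pattern = pattern, decenter_mm = as.numeric(decenter_mm),
                 noise_sd_um = noise_sd_um,
                 noise_correlation_mm = noise_correlation_mm,
                 blip_rate = blip_rate,
                 blip_amplitude_um = blip_amplitude_um,
                 seed = as.integer(seed)),
            class = "acquisition_config")
}

# correlated noise along one B-scan: white noise convolved with a
# Gaussian kernel of the stated correlation length, rescaled to sd
correlated_noise <- function(n, sd_um, corr_samples) {
  if (sd_um == 0) return(numeric(n))
  half <- max(1L, ceiling(3 * corr_samples))
  kern <- exp(-((-half):half)^2 / (2 * corr_samples^2))
  w <- rnorm(n + 2L * half)
  sm <- as.numeric(stats::filter(w, kern, sides = 2L))
  sm <- sm[(half + 1L):(half + n)]
  sm * sd_um / sqrt(sum(kern^2))
}

scan_lattice <- function(pattern, n_bscans, n_ascans) {
  if (pattern == "raster") {
    xs <- seq(-4.5, 4.5, length.out = n_ascans)
    ys <- seq(-3.75, 3.75, length.out = n_bscans)
    list(x = rep(xs, n_bscans), y = rep(ys, each = n_ascans),
         bscan = rep(seq_len(n_bscans) - 1L, each = n_ascans),
         ascan = rep(seq_len(n_ascans) - 1L, n_bscans),
         field_radius = 3.75)
  } else {
    s <- seq(-2.25, 2.25, length.out = n_ascans)
    ang <- pi * (seq_len(n_bscans) - 1L) / n_bscans
    list(x = as.vector(vapply(ang, function(a) s * cos(a), numeric(n_ascans))),
         y = as.vector(vapply(ang, function(a) s * sin(a), numeric(n_ascans))),
         bscan = rep(seq_len(n_bscans) - 1L, each = n_ascans),
         ascan = rep(seq_len(n_ascans) - 1L, n_bscans),
         field_radius = 2.25)
  }
}

#' Simulate an OCT acquisition of a ground-truth surface
#'
#' Evaluates the true thickness surface at the A-scan positions of the
#' requested pattern, displaced by the fixation decentration, and adds
#' correlated per-B-scan noise plus sparse segmentation blips.  The scan
#' stores `ilm = TRT + noise` over a flat zero BM reference, so
#' [compute_trt()] recovers the noisy surface.
#'
#' @param truth A [make_surface()] result.
#' @param cfg An [acquisition_config()].
#' @return An [oct_scan()].
#' @export
sample_scan <- function(truth, cfg) {
  stopifnot(inherits(truth, "surface_truth"),
            inherits(cfg, "acquisition_config"))
  if (max(abs(cfg$decenter_mm)) > 0.6)
    stop("decentration pushes the pit outside the usable field",
         call. = FALSE)
  meta <- scan_meta(pattern = cfg$pattern, eye = "OD",
                    scan_id = paste0(cfg$pattern, "-", cfg$seed),
                    subject_id = "synthetic")
  lat <- scan_lattice(cfg$pattern, meta$n_bscans, meta$n_ascans)
  trt <- truth$fn(lat$x - cfg$decenter_mm[1L], lat$y - cfg$decenter_mm[2L])
  bscan_length <- if (cfg$pattern == "raster") 9.0 else 4.5
  spacing <- bscan_length / (meta$n_ascans - 1L)
  corr_samples <- cfg$noise_correlation_mm / spacing
  blip_run <- 5L  # segmentation errors span a few adjacent A-scans
  noise <- local_seed(cfg$seed, {
    nz <- unlist(lapply(seq_len(meta$n_bscans), function(b) {
      v <- correlated_noise(meta$n_ascans, cfg$noise_sd_um, corr_samples)
      if (cfg$blip_rate > 0 && cfg$blip_amplitude_um > 0) {
        start <- which(runif(meta$n_ascans) < cfg$blip_rate / blip_run)
        for (s in start) {
          span <- s:min(s + blip_run - 1L, meta$n_ascans)
          v[span] <- v[span] +
            cfg$blip_amplitude_um * sign(runif(1L) - 0.5)
        }
      }
      v
    }))
    nz
  })
  d <- data.frame(bscan_index = lat$bscan, ascan_index = lat$ascan,
                  x_mm = lat$x, y_mm = lat$y,
                  ilm_um = trt + noise, bm_um = 0)
  oct_scan(meta, d)
}

#' Simulate a cohort of paired raster/star acquisitions
#'
#' Draws per-eye pit shapes from documented synthetic distributions
#' (CFT ~ N(225, 20) um, pit depth ~ N(115, 15) um, rim radius ~
#' N(1.0, 0.15) mm, radial exponent ~ N(2, 0.25), perifoveal fraction ~
#' N(0.8, 0.05), harmonic modulation ~ N(0, 0.05); all spreads scaled by
#' `between_subject_sd`), an independent fixation decentration per
#' acquisition, and star noise `star_extra_noise_factor` times the
#' raster noise, emulating the visibly noisier star protocol.  Fully
#' deterministic under `seed`.
#'
#' @param n_eyes Number of eyes (>= 1).
#' @param between_subject_sd Multiplier on all between-subject spreads
#'   (0 makes every eye identical).
#' @param star_extra_noise_factor Star-to-raster noise ratio (default
#'   1.6).
#' @param decenter_sd_mm Per-axis SD of the fixation decentration,
#'   truncated at 0.25 mm per axis (default 0.12).
#' @param noise_sd_um Raster noise SD (default 2.5 um).
#' @param seed Integer seed.
#' @return A list of `n_eyes` elements, each holding `truth`, the
#'   `raster` and `star` [oct_scan()]s and their true decentrations.
#' @export
make_cohort <- function(n_eyes, between_subject_sd = 1,
                        star_extra_noise_factor = 1.6,
                        decenter_sd_mm = 0.12, noise_sd_um = 2.5,
                        seed = 1L) {
  stopifnot(n_eyes >= 1, between_subject_sd >= 0,
            star_extra_noise_factor > 0, decenter_sd_mm >= 0)
  bss <- between_subject_sd
  draw_trunc <- function(n, mean, sd, lo, hi)
    pmin(pmax(rnorm(n, mean, sd), lo), hi)
  local_seed(seed, {
    cft <- draw_trunc(n_eyes, 225, 20 * bss, 170, 280)
    depth <- draw_trunc(n_eyes, 115, 15 * bss, 70, 160)
    rimr <- draw_trunc(n_eyes, 1.0, 0.15 * bss, 0.6, 1.4)
    gam <- draw_trunc(n_eyes, 2, 0.25 * bss, 1.4, 2.8)
    afr <- draw_trunc(n_eyes, 0.8, 0.05 * bss, 0.6, 0.95)
    mods <- matrix(rnorm(4L * n_eyes, 0, 0.05 * bss), n_eyes, 4L)
    mods <- pmin(pmax(mods, -0.3), 0.3)
    dec <- matrix(pmin(pmax(rnorm(4L * n_eyes, 0, decenter_sd_mm),
                            -0.25), 0.25), n_eyes, 4L)
    scan_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                    2L * n_eyes), n_eyes, 2L)
    lapply(seq_len(n_eyes), function(i) {
      truth <- make_surface(list(
        cft_um = cft[i], rim_height_um = cft[i] + depth[i],
        rim_radius_mm = rimr[i], gamma = gam[i], alpha_frac = afr[i],
        modulation = list(mu_cos = mods[i, 1L], mu_sin = mods[i, 2L],
                          mu_cos2 = mods[i, 3L], alpha_cos = mods[i, 4L])))
      raster <- sample_scan(truth, acquisition_config(
        "raster", decenter_mm = dec[i, 1:2], noise_sd_um = noise_sd_um,
        seed = scan_seeds[i, 1L]))
      star <- sample_scan(truth, acquisition_config(
        "star", decenter_mm = dec[i, 3:4],
        noise_sd_um = noise_sd_um * star_extra_noise_factor,
        seed = scan_seeds[i, 2L]))
      list(truth = truth, raster = raster, star = star,
           decenter_raster = dec[i, 1:2], decenter_star = dec[i, 3:4])
    })
  })
}
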