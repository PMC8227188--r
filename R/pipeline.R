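# Study workflows: the centre-location comparison and the model
# comparison, run over a cohort of paired raster/star acquisitions.

scan_to_cloud <- function(scan) {
  standardize_orientation(compute_trt(scan), scan$meta$eye)
}

# carry the last defined value along each profile (then backwards for
# leading gaps); used for the rare far-field radial samples that fall
# outside a decentred star field
fill_profile_gaps <- function(values) {
  for (k in seq_len(nrow(values))) {
    v <- values[k, ]
    if (!anyNA(v)) next
    for (i in seq_along(v)) if (is.na(v[i]) && i > 1L) v[i] <- v[i - 1L]
    for (i in rev(seq_along(v))) if (is.na(v[i]) && i < length(v)) v[i] <- v[i + 1L]
    values[k, ] <- v
  }
  values
}

#' Compare foveal centre location strategies on a paired cohort
#'
#' For every eye and every strategy, both acquisitions are centred
#' independently on their own centre estimate, resampled to the common
#' regular grid, and scored with the alignment dissimilarity
#' [dalign()].  Per-method distributions are summarized by median and
#' interquartile range and compared with Kruskal-Wallis and pairwise
#' Mann-Whitney tests.  When the cohort carries true decentrations
#' (synthetic data), per-method localization errors are reported too.
#'
#' @param cohort A [make_cohort()] result, or any list of elements with
#'   `raster` and `star` [oct_scan()]s.
#' @param config Optional list: `methods` (default all four),
#'   `extent_mm` (3.0), `spacing_mm` (0.02), `alpha` (0.01).
#' @return A list with the per-eye dalign matrix, summary table,
#'   rank-based tests, and (when available) localization errors.
#' @export
run_center_comparison <- function(cohort, config = list()) {
  cfg <- utils::modifyList(list(
    methods = c("none", "min", "interp_min", "smooth_min"),
    extent_mm = 3.0, spacing_mm = 0.02, alpha = 0.01), config)
  n <- length(cohort)
  dal <- matrix(NA_real_, n, length(cfg$methods),
                dimnames = list(NULL, cfg$methods))
  loc_err <- matrix(NA_real_, 2L * n, length(cfg$methods),
                    dimnames = list(NULL, cfg$methods))
  has_truth <- all(vapply(cohort, function(e)
    !is.null(e$decenter_raster), logical(1L)))
  for (i in seq_len(n)) {
    eye <- cohort[[i]]
    if (is.null(eye$raster) || is.null(eye$star)) {
      warning("eye ", i, " is unpaired; skipped", call. = FALSE)
      next
    }
    cl_r <- scan_to_cloud(eye$raster)
    cl_s <- scan_to_cloud(eye$star)
    for (m in cfg$methods) {
      ctr_r <- locate_center(cl_r, m)
      ctr_s <- locate_center(cl_s, m)
      g_r <- resample_regular(recenter(cl_r, ctr_r), cfg$extent_mm,
                              cfg$spacing_mm)
      g_s <- resample_regular(recenter(cl_s, ctr_s), cfg$extent_mm,
                              cfg$spacing_mm)
      dal[i, m] <- dalign(g_r, g_s)
      if (has_truth) {
        loc_err[2L * i - 1L, m] <- sqrt(sum((c(ctr_r$x_mm, ctr_r$y_mm) -
                                               eye$decenter_raster)^2))
        loc_err[2L * i, m] <- sqrt(sum((c(ctr_s$x_mm, ctr_s$y_mm) -
                                          eye$decenter_star)^2))
      }
    }
  }
  keep <- stats::complete.cases(dal)
  dal <- dal[keep, , drop = FALSE]
  summary_tbl <- data.frame(
    method = cfg$methods,
    median_um = apply(dal, 2L, median),
    iqr_low_um = apply(dal, 2L, quantile, 0.25),
    iqr_high_um = apply(dal, 2L, quantile, 0.75),
    row.names = NULL)
  tests <- if (nrow(dal) >= 3L)
    compare_distributions(
      setNames(lapply(cfg$methods, function(m) dal[, m]), cfg$methods),
      alpha = cfg$alpha)
  else NULL  # rank tests need at least 3 paired eyes
  out <- list(dalign_um = dal, summary = summary_tbl, tests = tests,
              config = cfg)
  if (has_truth) {
    out$localization_error_mm <- loc_err
    out$median_localization_error_mm <-
      apply(loc_err, 2L, median, na.rm = TRUE)
  }
  out
}

eye_radial <- function(scan, radius_mm = 2.0, n_directions = 24L,
                       step_mm = 0.02) {
  cloud <- scan_to_cloud(scan)
  ctr <- locate_smooth_min(cloud)
  prof <- resample_radial(recenter(cloud, ctr), radius_mm, n_directions,
                          step_mm)
  if (anyNA(prof$values_um))
    prof$values_um <- fill_profile_gaps(prof$values_um)
  prof
}

param_names <- c("cft", "rim_height", "rim_radius", "max_slope")

params_vector <- function(p) {
  c(cft = p$cft_um, rim_height = p$mean_rim_height_um,
    rim_radius = p$mean_rim_radius_mm, max_slope = p$mean_max_slope_um_mm)
}

#' Compare pit models and smoothers on a paired cohort
#'
#' Both acquisitions of every eye are centred with the smooth + min
#' strategy and resampled to the 24-direction radial pattern.  Raw pit
#' parameters are computed, every configured model/smoother is fitted,
#' and each approach is scored by fitting RMSE (mean and SD, raster and
#' star separately), raster-star agreement per parameter (ICC(2,1) with
#' a seeded percentile-bootstrap CI) and relative estimation bias per
#' parameter (mean and SD; `NA` where the model pins the parameter to
#' the raw estimate).  A LOESS span sweep provides the ICC-versus-bias
#' trade-off curve.  Non-converged fits are excluded and counted.
#'
#' @param cohort A [make_cohort()]-style list of paired scans.
#' @param config Optional list: `approaches` (named list of
#'   [model_spec()]s; default the six models plus LOESS at 20% and
#'   50%), `loess_sweep` (spans for the trade-off curve; default
#'   `seq(0.1, 0.5, 0.1)`, `NULL` to skip), `n_boot` (default 10000),
#'   `seed` (bootstrap seed, default 1).
#' @return A list with the RMSE, ICC and bias tables, the per-eye
#'   parameter arrays, the sweep curve data and convergence counts.
#' @export
run_model_comparison <- function(cohort, config = list()) {
  default_apps <- list(
    dubis = model_spec("dubis"), ding = model_spec("ding"),
    scheibe = model_spec("scheibe"), liu = model_spec("liu"),
    yadav = model_spec("yadav"), breher = model_spec("breher"),
    loess_20 = model_spec("loess", span = 0.20),
    loess_50 = model_spec("loess", span = 0.50))
  cfg <- utils::modifyList(
    list(loess_sweep = seq(0.1, 0.5, 0.1), n_boot = 10000L, seed = 1L),
    config[setdiff(names(config), "approaches")])
  # replaced wholesale, never merged into the defaults
  apps <- if (!is.null(config$approaches)) config$approaches else default_apps
  cfg$approaches <- apps
  n <- length(cohort)
  protos <- c("raster", "star")
  sweep_ids <- if (length(cfg$loess_sweep))
    paste0("loess_sweep_", format(cfg$loess_sweep)) else character(0L)
  all_ids <- c("raw", names(apps), sweep_ids)
  params <- array(NA_real_, c(n, 2L, length(all_ids), 4L),
                  dimnames = list(NULL, protos, all_ids, param_names))
  rmse <- array(NA_real_, c(n, 2L, length(all_ids) - 1L),
                dimnames = list(NULL, protos, all_ids[-1L]))
  failed <- setNames(integer(length(apps)), names(apps))
  sweep_specs <- lapply(cfg$loess_sweep,
                        function(s) model_spec("loess", span = s))
  names(sweep_specs) <- sweep_ids
  fit_specs <- c(apps, sweep_specs)
  for (i in seq_len(n)) {
    for (pr in protos) {
      prof <- eye_radial(cohort[[i]][[pr]])
      raw <- suppressWarnings(compute_parameters(prof))
      params[i, pr, "raw", ] <- params_vector(raw)
      for (id in names(fit_specs)) {
        fit <- fit_model(prof, fit_specs[[id]])
        if (!fit$converged) {
          if (id %in% names(failed)) failed[id] <- failed[id] + 1L
          next
        }
        rmse[i, pr, id] <- fit$rmse_um
        pp <- suppressWarnings(parameters_from_fit(fit, prof))
        params[i, pr, id, ] <- params_vector(pp)
      }
    }
  }
  # RMSE table (mean +/- sd per protocol)
  rmse_tbl <- do.call(rbind, lapply(names(apps), function(id) {
    data.frame(approach = id,
               rmse_raster_mean = mean(rmse[, "raster", id], na.rm = TRUE),
               rmse_raster_sd = sd(rmse[, "raster", id], na.rm = TRUE),
               rmse_star_mean = mean(rmse[, "star", id], na.rm = TRUE),
               rmse_star_sd = sd(rmse[, "star", id], na.rm = TRUE))
  }))
  # ICC per approach x parameter, raw first; NA (dash) when the approach
  # cannot change the parameter
  fixed_mask <- function(id) {
    if (id == "raw") return(rep(FALSE, 4L))
    sp <- fit_specs[[id]]
    c(sp$fixes_center, sp$fixes_rim, sp$fixes_rim, FALSE)
  }
  icc_ids <- c("raw", names(apps))
  icc_tbl <- NULL
  boot_seeds <- local_seed(cfg$seed,
                           sample.int(.Machine$integer.max - 1L,
                                      length(icc_ids) * 4L))
  si <- 0L
  for (id in icc_ids) {
    row <- data.frame(approach = id)
    fx <- fixed_mask(id)
    for (j in seq_along(param_names)) {
      pn <- param_names[j]
      si <- si + 1L
      if (fx[j]) {
        row[[paste0("icc_", pn)]] <- NA_real_
        row[[paste0("icc_", pn, "_lo")]] <- NA_real_
        row[[paste0("icc_", pn, "_hi")]] <- NA_real_
        next
      }
      pairs <- cbind(params[, "raster", id, pn], params[, "star", id, pn])
      ok <- stats::complete.cases(pairs)
      # undefined ICC (too few converged eyes, degenerate variance) is
      # reported as NA rather than aborting the study
      est <- tryCatch(icc_2_1(pairs[ok, , drop = FALSE]),
                      error = function(e) NA_real_)
      ci <- if (is.na(est)) c(NA_real_, NA_real_) else
        tryCatch(bootstrap_ci(pairs[ok, , drop = FALSE], icc_2_1,
                              n_resamples = cfg$n_boot,
                              seed = boot_seeds[si]),
                 error = function(e) c(NA_real_, NA_real_))
      row[[paste0("icc_", pn)]] <- est
      row[[paste0("icc_", pn, "_lo")]] <- ci[1L]
      row[[paste0("icc_", pn, "_hi")]] <- ci[2L]
    }
    icc_tbl <- if (is.null(icc_tbl)) row else rbind(icc_tbl, row)
  }
  # bias per approach x parameter x protocol
  bias_of <- function(id, pn, pr) {
    relative_bias(params[, pr, id, pn], params[, pr, "raw", pn])
  }
  bias_tbl <- do.call(rbind, lapply(names(apps), function(id) {
    row <- data.frame(approach = id)
    fx <- fixed_mask(id)
    for (j in seq_along(param_names)) {
      pn <- param_names[j]
      for (pr in protos) {
        key <- paste0("bias_", pn, "_", pr)
        if (fx[j]) {
          row[[paste0(key, "_mean")]] <- NA_real_
          row[[paste0(key, "_sd")]] <- NA_real_
        } else {
          b <- bias_of(id, pn, pr)
          row[[paste0(key, "_mean")]] <- mean(b, na.rm = TRUE)
          row[[paste0(key, "_sd")]] <- sd(b, na.rm = TRUE)
        }
      }
    }
    row
  }))
  # LOESS sweep: ICC and mean bias per span (point estimates only)
  sweep_tbl <- NULL
  if (length(sweep_ids)) {
    sweep_tbl <- do.call(rbind, lapply(seq_along(sweep_ids), function(s) {
      id <- sweep_ids[s]
      row <- data.frame(span = cfg$loess_sweep[s])
      for (pn in param_names) {
        pairs <- cbind(params[, "raster", id, pn], params[, "star", id, pn])
        ok <- stats::complete.cases(pairs)
        row[[paste0("icc_", pn)]] <-
          tryCatch(icc_2_1(pairs[ok, , drop = FALSE]),
                   error = function(e) NA_real_)
        row[[paste0("bias_", pn, "_raster")]] <-
          mean(bias_of(id, pn, "raster"), na.rm = TRUE)
        row[[paste0("bias_", pn, "_star")]] <-
          mean(bias_of(id, pn, "star"), na.rm = TRUE)
      }
      row
    }))
  }
  list(rmse = rmse_tbl, icc = icc_tbl, bias = bias_tbl,
       loess_sweep = sweep_tbl, params = params, rmse_by_eye = rmse,
       failed_fits = failed, config = cfg)
}
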