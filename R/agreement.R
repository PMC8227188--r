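#' Alignment dissimilarity between two TRT maps
#'
#' Mean absolute thickness difference over the grid,
#' `(1/M) * sum |a - b|`, where `M` counts the cells defined in both
#' maps (all `N^2` cells when fully defined).  Used to score how well
#' two acquisitions of the same eye align after centring.
#'
#' @param a,b [trt_grid()] maps on identical axes.
#' @return Mean absolute difference in um.
#' @export
dalign <- function(a, b) {
  stopifnot(inherits(a, "trt_grid"), inherits(b, "trt_grid"))
  if (length(a$x_axis) != length(b$x_axis) ||
      max(abs(a$x_axis - b$x_axis)) > 1e-12 ||
      max(abs(a$y_axis - b$y_axis)) > 1e-12)
    stop("grids are not on identical axes", call. = FALSE)
  d <- abs(a$values_um - b$values_um)
  mean(d, na.rm = TRUE)
}

#' Fitting root-mean-square error
#'
#' `sqrt(mean((raw - fitted)^2))` over the cells/samples defined in both
#' inputs.  Accepts a pair of [trt_grid()]s, a pair of
#' [radial_profiles()], or two equal-shaped matrices.
#'
#' @param raw,fitted Matching containers of thickness values.
#' @return RMSE in um.
#' @export
fitting_rmse <- function(raw, fitted) {
  va <- extract_values(raw); vb <- extract_values(fitted)
  if (!identical(dim(va), dim(vb)))
    stop("inputs have mismatched shapes", call. = FALSE)
  sqrt(mean((va - vb)^2, na.rm = TRUE))
}

extract_values <- function(x) {
  if (inherits(x, "trt_grid") || inherits(x, "radial_profiles"))
    return(x$values_um)
  if (inherits(x, "pit_fit")) return(x$fitted_values_um)
  as.matrix(x)
}

#' Relative estimation bias
#'
#' `100 * (x_model - x_raw) / x_raw` in percent; negative values mean
#' the model underestimates the raw parameter.
#'
#' @param x_model,x_raw Parameter estimates after and before modelling.
#' @return Bias in percent.
#' @export
relative_bias <- function(x_model, x_raw) {
  if (any(x_raw == 0)) stop("relative bias undefined for x_raw = 0", call. = FALSE)
  100 * (x_model - x_raw) / x_raw
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way, absolute-agreement, single-measurement intraclass
#' correlation by the mean-squares formulation:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with `MSR` the between-subject, `MSC` the between-rater and `MSE`
#' the residual mean square, `n` subjects and `k` raters.
#'
#' @param pairs Numeric matrix with one row per subject (eye) and one
#'   column per rater/protocol (k = 2 for raster vs star).
#' @return The ICC point estimate.
#' @export
icc_2_1 <- function(pairs) {
  pairs <- as.matrix(pairs)
  n <- nrow(pairs); k <- ncol(pairs)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (!all(is.finite(pairs))) stop("pairs must be finite", call. = FALSE)
  grand <- mean(pairs)
  row_m <- rowMeans(pairs); col_m <- colMeans(pairs)
  ss_total <- sum((pairs - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  if (ss_total <= 0) stop("zero total variance: ICC undefined", call. = FALSE)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples subjects (rows) with replacement, keeping each row's
#' protocol pairing intact, and returns the 2.5 and 97.5 percentiles of
#' the statistic's bootstrap distribution.  Fully seeded: identical
#' seeds give identical intervals.
#'
#' @param pairs Numeric matrix, one row per subject.
#' @param statistic Function of a resampled matrix returning a scalar
#'   (default [icc_2_1()]).
#' @param n_resamples Number of bootstrap resamples (default 10000).
#' @param seed Integer seed for the resampling.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(pairs, statistic = icc_2_1, n_resamples = 10000L,
                         seed = 1L, level = 0.95) {
  pairs <- as.matrix(pairs)
  n <- nrow(pairs)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  stats_boot <- local_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(statistic(pairs[idx, , drop = FALSE]),
               error = function(e) NA_real_)
    }, numeric(1L))
  })
  if (mean(is.na(stats_boot)) > 0.5)
    stop("statistic undefined on more than half of the resamples",
         call. = FALSE)
  alpha <- (1 - level) / 2
  as.numeric(quantile(stats_boot, c(alpha, 1 - alpha), na.rm = TRUE,
                      names = FALSE))
}

# evaluate expr under a temporary RNG state, restoring the caller's
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Rank-based comparison of value distributions
#'
#' Kruskal-Wallis test across all groups, pairwise Mann-Whitney U tests
#' (exact for small untied samples, normal approximation with tie
#' correction otherwise, as in [wilcox.test()]), and a Shapiro-Wilk
#' normality screen per group.  Differences are flagged at the 0.01
#' significance level.
#'
#' @param groups Named list of at least two numeric vectors (each of
#'   length >= 3).
#' @param alpha Significance level for flagging (default 0.01).
#' @return A list with the Kruskal-Wallis statistic and p-value, a data
#'   frame of pairwise tests, per-group Shapiro-Wilk p-values, and the
#'   flagging level.
#' @export
compare_distributions <- function(groups, alpha = 0.01) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(!vapply(groups, length, 1L) >= 3L))
    stop("every group needs at least 3 values", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  kw <- kruskal.test(groups)
  cmb <- utils::combn(names(groups), 2L)
  pw <- data.frame(group1 = cmb[1L, ], group2 = cmb[2L, ],
                   u_statistic = NA_real_, p_value = NA_real_)
  for (i in seq_len(ncol(cmb))) {
    mw <- suppressWarnings(
      wilcox.test(groups[[cmb[1L, i]]], groups[[cmb[2L, i]]]))
    pw$u_statistic[i] <- unname(mw$statistic)
    pw$p_value[i] <- mw$p.value
  }
  pw$significant <- pw$p_value < alpha
  sw <- vapply(groups, function(g) {
    if (length(unique(g)) < 3L || length(g) < 3L) return(NA_real_)
    suppressWarnings(shapiro.test(g)$p.value)
  }, numeric(1L))
  list(kruskal_statistic = unname(kw$statistic),
       kruskal_p = kw$p.value,
       kruskal_significant = kw$p.value < alpha,
       pairwise = pw,
       shapiro_p = sw,
       alpha = alpha)
}
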