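#' LOESS smoothing of a thickness profile
#'
#' Local quadratic regression with tricube weights over the nearest
#' `span_fraction * n` samples at each point (applied per diametric
#' profile when used through [fit_model()]).  A second-degree local fit
#' reproduces globally quadratic profiles exactly.
#'
#' @param profile Numeric vector of uniformly spaced samples.
#' @param span_fraction Fraction of samples in each local window, in
#'   `[0.01, 0.50]`.
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_loess <- function(profile, span_fraction) {
  if (!is.numeric(span_fraction) || length(span_fraction) != 1L ||
      span_fraction < 0.01 || span_fraction > 0.50)
    stop("span_fraction must lie in [0.01, 0.50]", call. = FALSE)
  n <- length(profile)
  if (n < max(5, span_fraction * n))
    stop("profile too short for the requested span", call. = FALSE)
  if (floor(span_fraction * n) < 4L)
    stop("span covers fewer than 4 samples; increase span_fraction",
         call. = FALSE)
  x <- seq_len(n)
  fit <- stats::loess(profile ~ x, span = span_fraction, degree = 2L,
                      family = "gaussian", surface = "direct")
  as.numeric(stats::predict(fit, newdata = data.frame(x = x)))
}

#' Moving-average smoothing of a thickness profile
#'
#' Centred mean over `window` samples, with the window truncated and
#' renormalized at the profile edges.  Even windows take one extra
#' sample on the left.
#'
#' @param profile Numeric vector of uniformly spaced samples.
#' @param window Integer window length in `[5, 60]`, at most the profile
#'   length.
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_movavg <- function(profile, window) {
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 5L || window > 60L)
    stop("window must be an integer in [5, 60]", call. = FALSE)
  n <- length(profile)
  if (window > n) stop("window exceeds the profile length", call. = FALSE)
  left <- ceiling((window - 1L) / 2L)
  right <- window - 1L - left
  cs <- cumsum(c(0, profile))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L); hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
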