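#' Rescaled-range (R/S) estimate of the Hurst exponent
#'
#' Classical Mandelbrot--Wallis rescaled-range analysis. For each window
#' size the series is cut into non-overlapping segments; within a segment
#' the range of the mean-adjusted cumulative sum is divided by the segment
#' standard deviation, and the segment values are averaged. The Hurst
#' exponent is the ordinary least-squares slope of log2(R/S) against
#' log2(window size) over a geometric schedule of window sizes.
#'
#' The raw regression slope can fall outside [0, 1] on short or strongly
#' trended records; the reported `H` is clamped to [0, 1] (the admissible
#' range of the diffusion model) and the raw slope is kept alongside.
#'
#' @param x Numeric vector or [eeg_series()]. Must be non-constant, with
#'   length >= max(16, 2 * min_window).
#' @param min_window Smallest window size in samples (default 16: segments shorter than
#'   this are dropped because the expected R/S of short segments deviates
#'   most from the asymptotic power law, biasing the slope upward).
#' @param max_window Largest window size (default `length(x) / 2`).
#' @param n_scales Number of window sizes on the geometric schedule
#'   (default 10; at least 3 distinct sizes are required).
#' @param detrend Segment detrending: `"mean"` (classical R/S,
#'   mean-adjustment only, the default) or `"linear"` (remove an OLS line
#'   within each segment before accumulating).
#' @return An object of class `hurst_estimate`: a list with `H` (clamped to
#'   [0, 1]), `raw_slope`, `slope_stderr`, `n_scales`, `window_sizes` and a
#'   data frame `rs` of per-scale mean R/S values.
#' @examples
#' set.seed(1)
#' rs_hurst(rnorm(4096))  # white noise: H near 0.5
#' @export
rs_hurst <- function(x, min_window = 16L, max_window = NULL, n_scales = 10L,
                     detrend = c("mean", "linear")) {
  detrend <- match.arg(detrend)
  if (inherits(x, "eeg_series")) x <- x$values
  x <- as.numeric(x)
  n <- length(x)
  min_window <- as.integer(min_window)
  if (min_window < 4L) stop("'min_window' must be >= 4")
  if (is.null(max_window)) max_window <- floor(n / 2)
  max_window <- as.integer(max_window)
  if (n < max(16L, 2L * min_window))
    stop("series too short for R/S analysis: need at least ",
         max(16L, 2L * min_window), " samples, got ", n)
  if (min_window >= max_window || max_window > n)
    stop("need min_window < max_window <= length(x)")
  if (stats::sd(x) == 0)
    stop("degenerate input: constant series has undefined rescaled range")

  ws <- unique(round(2^seq(log2(min_window), log2(max_window),
                           length.out = n_scales)))
  rs <- vapply(ws, function(w) rs_statistic(x, w, detrend), numeric(1))
  keep <- is.finite(rs) & rs > 0
  ws <- ws[keep]; rs <- rs[keep]
  if (length(ws) < 3L)
    stop("fewer than 3 usable scales; series is too short or too degenerate")

  fit <- stats::lm(log2(rs) ~ log2(ws))
  slope <- unname(stats::coef(fit)[2L])
  stderr <- unname(summary(fit)$coefficients[2L, 2L])
  structure(list(H = min(1, max(0, slope)),
                 raw_slope = slope,
                 slope_stderr = stderr,
                 n_scales = length(ws),
                 window_sizes = ws,
                 rs = data.frame(window = ws, rs = rs)),
            class = "hurst_estimate")
}

# Mean R/S over the non-overlapping segments of length w; segments with
# zero standard deviation are skipped.
rs_statistic <- function(x, w, detrend = "mean") {
  k <- floor(length(x) / w)
  segs <- matrix(x[seq_len(k * w)], nrow = w)
  vals <- apply(segs, 2L, function(s) {
    if (detrend == "linear") {
      i <- seq_along(s)
      s <- stats::residuals(stats::lm.fit(cbind(1, i), s))
    }
    sdev <- stats::sd(s)
    if (!is.finite(sdev) || sdev == 0) return(NA_real_)
    y <- cumsum(s - mean(s))
    (max(y) - min(y)) / sdev
  })
  mean(vals, na.rm = TRUE)
}

#' @export
print.hurst_estimate <- function(x, ...) {
  cat(sprintf("<hurst_estimate> H = %.4f (raw slope %.4f +/- %.4f, %d scales)\n",
              x$H, x$raw_slope, x$slope_stderr, x$n_scales))
  invisible(x)
}

#' Sliding-window Hurst trajectory
#'
#' Runs [rs_hurst()] over sliding windows of a series, producing a
#' time-indexed trajectory of Hurst-exponent estimates. Each estimate is
#' timestamped at the window's trailing edge (the time of the last sample
#' in the window), so the value at time t uses only data up to t.
#'
#' @param series An [eeg_series()] or numeric vector (a vector is assumed
#'   sampled at `sampling_rate`).
#' @param window_length Window length in samples; must be at least twice
#'   the smallest R/S scale.
#' @param step Window step in samples (default 1).
#' @param sampling_rate Sampling rate used when `series` is a bare vector.
#' @param min_window,n_scales Passed to [rs_hurst()]; the per-window
#'   maximum scale is `window_length / 2`.
#' @return A data frame of class `hurst_trajectory` with columns `time_s`
#'   and `H` (clamped to [0, 1]); attributes `window_length` and `step`.
#' @export
sliding_hurst <- function(series, window_length, step = 1L,
                          sampling_rate = 256, min_window = 16L,
                          n_scales = 10L) {
  if (!inherits(series, "eeg_series"))
    series <- eeg_series(series, sampling_rate)
  x <- series$values
  n <- length(x)
  window_length <- as.integer(window_length)
  step <- as.integer(step)
  if (step < 1L) stop("'step' must be >= 1")
  if (window_length > n)
    stop("window_length (", window_length, ") exceeds series length (", n, ")")
  if (window_length < 2L * min_window)
    stop("window_length must be at least 2 * min_window = ", 2L * min_window)

  starts <- seq.int(1L, n - window_length + 1L, by = step)
  # window i covers samples i .. i + window_length - 1; the trailing-edge
  # timestamp is the time of that last sample
  times <- series$t0 + (starts + window_length - 2L) / series$sampling_rate
  H <- vapply(starts, function(i) {
    rs_hurst(x[i:(i + window_length - 1L)], min_window = min_window,
             max_window = floor(window_length / 2), n_scales = n_scales)$H
  }, numeric(1))
  out <- data.frame(time_s = times, H = pmin(1, pmax(0, H)))
  attr(out, "window_length") <- window_length
  attr(out, "step") <- step
  class(out) <- c("hurst_trajectory", "data.frame")
  out
}

#' Reflect a Hurst exponent into the reference span [0.5, 1]
#'
#' A process with Hurst exponent H on one side of 0.5 has the mirrored
#' exponent H' = 1 - H on the other side with the same fluctuation
#' magnitude, so magnitude computations are carried out on the reference
#' span [0.5, 1]: values below 0.5 are mapped to 1 - H, values at or above
#' 0.5 are returned unchanged.
#'
#' @param H Numeric vector with all values in [0, 1].
#' @return Values in [0.5, 1]. Idempotent: `reflect_h(reflect_h(H))`
#'   equals `reflect_h(H)`.
#' @examples
#' reflect_h(0.2)   # 0.8
#' reflect_h(0.75)  # unchanged
#' @export
reflect_h <- function(H) {
  if (any(!is.finite(H)) || any(H < 0) || any(H > 1))
    stop("H must lie in [0, 1]")
  ifelse(H >= 0.5, H, 1 - H)
}

#' Direction of the next deflection from the Hurst exponent
#'
#' For a persistent process (H > 0.5) the next deflection keeps the
#' previous trend; for an antipersistent process (H < 0.5) it reverses it.
#' At exactly H = 0.5 the process carries no correlation, so the direction
#' is a fair coin flip (seedable for reproducibility).
#'
#' @param H Hurst exponent in [0, 1].
#' @param previous_trend +1 or -1.
#' @param seed Optional integer seed for the H = 0.5 coin flip; when
#'   `NULL` the current RNG stream is used.
#' @return +1 or -1.
#' @export
trend_direction <- function(H, previous_trend, seed = NULL) {
  if (!is.finite(H) || H < 0 || H > 1) stop("H must lie in [0, 1]")
  if (!previous_trend %in% c(-1, 1)) stop("previous_trend must be +1 or -1")
  if (H > 0.5) return(previous_trend)
  if (H < 0.5) return(-previous_trend)
  with_seed(seed, sample(c(-1, 1), 1L))
}
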