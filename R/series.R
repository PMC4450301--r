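#' Uniformly sampled voltage time series
#'
#' The basic container for all signals handled by the package: a vector of
#' voltages (microvolts) sampled at a fixed rate, together with the time of
#' the first sample and, optionally, the time at which the stimulus was
#' applied. All downstream stages (Hurst tracking, response prediction,
#' feature extraction) operate on this class.
#'
#' @param values Numeric vector of voltages in microvolts, length >= 1.
#' @param sampling_rate Samples per second, > 0.
#' @param t0 Time of the first sample in seconds (default 0).
#' @param stimulus_onset Time of stimulus application in seconds, or `NULL`
#'   when no stimulus marker exists. Must fall within the sampled interval.
#' @return An object of class `eeg_series`.
#' @examples
#' s <- eeg_series(sin(seq(0, 2, length.out = 512)), sampling_rate = 256,
#'                 stimulus_onset = 1)
#' s
#' @export
eeg_series <- function(values, sampling_rate, t0 = 0, stimulus_onset = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("'values' must have length >= 1")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("'sampling_rate' must be a single positive number")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("'t0' must be a single finite number")
  t_end <- t0 + (length(values) - 1L) / sampling_rate
  if (!is.null(stimulus_onset)) {
    if (!is.numeric(stimulus_onset) || length(stimulus_onset) != 1L ||
        !is.finite(stimulus_onset))
      stop("'stimulus_onset' must be a single finite number or NULL")
    if (stimulus_onset < t0 - 1e-12 || stimulus_onset > t_end + 1e-12)
      stop("'stimulus_onset' must lie within the sampled interval [",
           t0, ", ", t_end, "]")
  }
  structure(list(values = values, sampling_rate = sampling_rate, t0 = t0,
                 stimulus_onset = stimulus_onset),
            class = "eeg_series")
}

#' @export
print.eeg_series <- function(x, ...) {
  cat(sprintf("<eeg_series> %d samples @ %g Hz, t = [%g, %g] s",
              length(x$values), x$sampling_rate, x$t0,
              x$t0 + (length(x$values) - 1L) / x$sampling_rate))
  if (!is.null(x$stimulus_onset))
    cat(sprintf(", stimulus at %g s", x$stimulus_onset))
  cat("\n")
  invisible(x)
}

#' @export
length.eeg_series <- function(x) length(x$values)

#' @export
as.data.frame.eeg_series <- function(x, ...) {
  data.frame(time_s = series_times(x), value_uV = x$values)
}

#' Sample times of a series
#'
#' @param series An [eeg_series()].
#' @return Numeric vector of sample times in seconds.
#' @export
series_times <- function(series) {
  stopifnot(inherits(series, "eeg_series"))
  series$t0 + (seq_along(series$values) - 1L) / series$sampling_rate
}

# Index of the sample at (or nearest to) time t.
sample_index_at <- function(series, t) {
  i <- round((t - series$t0) * series$sampling_rate) + 1L
  max(1L, min(length(series$values), i))
}

#' Pre- and post-stimulus segments
#'
#' `post_stimulus()` returns the segment from the stimulus onset (inclusive)
#' to the end of the record; `pre_stimulus()` the segment strictly before
#' the onset. Both preserve the sampling metadata.
#'
#' @param series An [eeg_series()] with a stimulus marker.
#' @return An [eeg_series()].
#' @export
post_stimulus <- function(series) {
  stopifnot(inherits(series, "eeg_series"))
  if (is.null(series$stimulus_onset))
    stop("series has no stimulus_onset marker")
  i <- sample_index_at(series, series$stimulus_onset)
  eeg_series(series$values[i:length(series$values)], series$sampling_rate,
             t0 = series$t0 + (i - 1L) / series$sampling_rate,
             stimulus_onset = series$stimulus_onset)
}

#' @rdname post_stimulus
#' @export
pre_stimulus <- function(series) {
  stopifnot(inherits(series, "eeg_series"))
  if (is.null(series$stimulus_onset))
    stop("series has no stimulus_onset marker")
  i <- sample_index_at(series, series$stimulus_onset)
  if (i <= 1L) stop("no samples before the stimulus onset")
  eeg_series(series$values[1:(i - 1L)], series$sampling_rate, t0 = series$t0)
}

# Run `expr` under a temporary RNG seed without disturbing the caller's RNG
# stream; with seed = NULL the current stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
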