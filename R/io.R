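#' Read a signal from disk
#'
#' Two plain-text interchange formats are supported: `txt`, one voltage
#' per line (the sampling rate must then be supplied), and `csv` with
#' columns `time_s` and `value_uV`, from which the sampling rate is
#' inferred after checking that the time base is uniform to 1 ppm.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"txt"` or `"csv"`.
#' @param sampling_rate Samples per second; required for `txt`.
#' @param t0 Time of the first sample for `txt` input (default 0).
#' @param stimulus_onset Optional stimulus marker in seconds.
#' @return An [eeg_series()].
#' @export
read_signal <- function(path, format = c("auto", "txt", "csv"),
                        sampling_rate = NULL, t0 = 0,
                        stimulus_onset = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"

  if (format == "txt") {
    if (is.null(sampling_rate))
      stop("missing parameter 'sampling_rate': required for txt input")
    lines <- readLines(path)
    lines <- lines[seq_len(max(0L, Position(nzchar, trimws(lines),
                                            right = TRUE, nomatch = 0L)))]
    if (length(lines) == 0L) stop("parse error: '", path, "' is empty")
    vals <- suppressWarnings(as.numeric(lines))
    bad <- which(is.na(vals))
    if (length(bad) > 0L)
      stop("parse error in '", path, "': non-numeric value at line ", bad[1L])
    return(eeg_series(vals, sampling_rate, t0 = t0,
                      stimulus_onset = stimulus_onset))
  }

  df <- utils::read.csv(path)
  if (!all(c("time_s", "value_uV") %in% names(df)))
    stop("format error: csv must have columns time_s, value_uV")
  if (nrow(df) < 2L) stop("parse error: need at least 2 samples")
  dts <- diff(df$time_s)
  dt <- stats::median(dts)
  if (dt <= 0 || max(abs(dts - dt)) > 1e-6 * dt)
    stop("format error: csv time base not uniform to 1 ppm")
  eeg_series(df$value_uV, sampling_rate = 1 / dt, t0 = df$time_s[1L],
             stimulus_onset = stimulus_onset)
}

#' Write a signal to disk
#'
#' Values are formatted with 17 significant digits, so a write-read round
#' trip reproduces the doubles exactly.
#'
#' @param series An [eeg_series()].
#' @param path Output file.
#' @param format `"auto"` (by extension), `"txt"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_signal <- function(series, path, format = c("auto", "txt", "csv")) {
  stopifnot(inherits(series, "eeg_series"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  if (format == "txt") {
    writeLines(sprintf("%.17g", series$values), path)
  } else {
    df <- data.frame(time_s = sprintf("%.17g", series_times(series)),
                     value_uV = sprintf("%.17g", series$values))
    utils::write.table(df, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Standard EEG preprocessing band (default 0.1--70 Hz): a Butterworth
#' bandpass of the given order applied forward and backward
#' (zero phase), with odd-reflection padding at both ends to suppress
#' edge transients. Length is preserved.
#'
#' @param series An [eeg_series()].
#' @param low,high Band edges in Hz; `0 <= low < high < rate / 2`. A zero
#'   `low` edge degenerates to a lowpass.
#' @param order Filter order (default 4).
#' @return The filtered [eeg_series()].
#' @export
bandpass <- function(series, low = 0.1, high = 70, order = 4L) {
  stopifnot(inherits(series, "eeg_series"))
  fs <- series$sampling_rate
  if (!(low >= 0 && low < high && high < fs / 2))
    stop("invalid band: need 0 <= low < high < sampling_rate / 2")
  flt <- if (low > 0)
    signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  else
    signal::butter(order, high / (fs / 2), type = "low")
  x <- series$values
  n <- length(x)
  p <- min(n - 1L, as.integer(3 * fs))
  padded <- if (p > 0L)
    c(2 * x[1L] - rev(x[2L:(p + 1L)]), x, 2 * x[n] - rev(x[(n - p):(n - 1L)]))
  else x
  y <- signal::filtfilt(flt, padded)
  y <- y[(p + 1L):(p + n)]
  eeg_series(y, fs, t0 = series$t0, stimulus_onset = series$stimulus_onset)
}

#' Wavelet-shrinkage denoising
#'
#' Discrete wavelet denoising with the classical universal threshold:
#' the signal is decomposed with a periodised orthogonal DWT (db4, 4
#' levels by default), the noise level is estimated from the finest
#' detail coefficients as MAD / 0.6745, all detail levels are
#' soft-thresholded at sigma * sqrt(2 log n), and the signal is
#' reconstructed. Soft thresholding never increases coefficient energy.
#' Records whose length is not a multiple of 2^levels are reflection-
#' padded at the end and truncated after reconstruction.
#'
#' @param series An [eeg_series()] of length >= 64.
#' @param wavelet `"db4"` (default) or `"haar"`.
#' @param levels Decomposition depth (default 4).
#' @return The denoised [eeg_series()].
#' @export
wavelet_denoise <- function(series, wavelet = "db4", levels = 4L) {
  stopifnot(inherits(series, "eeg_series"))
  x <- series$values
  n <- length(x)
  if (n < 64L) stop("series too short for wavelet denoising: need >= 64")
  block <- 2L^levels
  n_pad <- (block - n %% block) %% block
  if (n_pad > 0L) x <- c(x, rev(x)[seq_len(n_pad)])
  dec <- dwt_periodic(x, wavelet, levels)
  sigma <- stats::mad(dec$details[[1L]], center = 0, constant = 1) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  dec$details <- lapply(dec$details, soft_threshold, thr = thr)
  y <- idwt_periodic(dec)[seq_len(n)]
  eeg_series(y, series$sampling_rate, t0 = series$t0,
             stimulus_onset = series$stimulus_onset)
}
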