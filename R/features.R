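#' Evoked-response features
#'
#' Constructor for the feature bundle that characterises an evoked
#' response: initiation latency (ms post-stimulus), response duration (s),
#' peak-to-peak voltage (uV) and the latencies of the P and N peaks
#' (s post-stimulus). Used both by [detect_response()] and directly when
#' building comparison tables from reported values.
#'
#' @param initiation_ms Initiation latency in milliseconds post-stimulus.
#' @param duration_s Response duration in seconds, >= 0.
#' @param peak_to_peak_uV Peak-to-peak voltage in microvolts, >= 0.
#' @param p_time_s,n_time_s P/N latencies in seconds post-stimulus
#'   (optional; `p_time_s <= n_time_s` when both are given).
#' @param detected Whether a response was found (default `TRUE`).
#' @return An object of class `response_features`.
#' @export
response_features <- function(initiation_ms = NA_real_,
                              duration_s = NA_real_,
                              peak_to_peak_uV = NA_real_,
                              p_time_s = NA_real_, n_time_s = NA_real_,
                              detected = TRUE) {
  if (is.finite(duration_s) && duration_s < 0)
    stop("'duration_s' must be >= 0")
  if (is.finite(peak_to_peak_uV) && peak_to_peak_uV < 0)
    stop("'peak_to_peak_uV' must be >= 0")
  if (is.finite(p_time_s) && is.finite(n_time_s) && p_time_s > n_time_s)
    stop("'p_time_s' must be <= 'n_time_s'")
  structure(list(initiation_ms = initiation_ms, duration_s = duration_s,
                 peak_to_peak_uV = peak_to_peak_uV, p_time_s = p_time_s,
                 n_time_s = n_time_s, detected = detected),
            class = "response_features")
}

#' @export
print.response_features <- function(x, ...) {
  if (!x$detected) {
    cat("<response_features> no response detected\n")
  } else {
    cat(sprintf("<response_features> P at %.1f ms, duration %.3f s, peak-to-peak %.2f uV\n",
                x$initiation_ms, x$duration_s, x$peak_to_peak_uV))
  }
  invisible(x)
}

# Strict local extrema of a vector: indices where the first difference
# changes sign. Zero first differences (plateaus) carry the last non-zero
# slope forward, so a plateau is not itself an extremum.
local_extrema <- function(v) {
  d <- diff(v)
  s <- sign(d)
  for (i in seq_along(s)[-1L]) if (s[i] == 0) s[i] <- s[i - 1L]
  idx <- which(s[-1L] != 0 & s[-length(s)] != 0 & s[-1L] != s[-length(s)]) + 1L
  if (length(idx) == 0L)
    return(data.frame(index = integer(0), value = numeric(0),
                      type = character(0)))
  data.frame(index = idx, value = v[idx],
             type = ifelse(s[idx - 1L] > 0, "max", "min"))
}

#' Detect the evoked response and extract its features
#'
#' Screens the local extrema of the post-stimulus segment against the
#' response voltage bands (by default 5 to 10 uV for positive peaks and
#' -10 to -5 uV for negative ones). An extremum qualifies when its
#' magnitude reaches the near edge of a band; values beyond the far edge
#' also qualify, since observed peak-to-peak excursions routinely exceed
#' the band's upper edge. The initiation time is the latency of the first
#' qualifying peak (the response starts with a positive peak P); the
#' response ends at the last qualifying peak, and the duration is the time
#' span between the two. When only one extremum qualifies, the terminating
#' negative rebound N is taken as the most negative local extremum after
#' the first qualifying peak, whatever its depth, because the response
#' terminates at the rebound even when the rebound itself falls short of
#' the band. Peak-to-peak voltage is max - min over the \[first, last\]
#' window. Bands are absolute voltages, not baseline-relative; set
#' `baseline_correct = TRUE` to subtract the mean of the pre-stimulus
#' segment first.
#'
#' @param series An [eeg_series()] with a stimulus marker.
#' @param pos_band Positive response band in uV (default `c(5, 10)`).
#' @param neg_band Negative response band in uV (default `c(-10, -5)`).
#' @param baseline_correct Subtract the pre-stimulus mean first
#'   (default `FALSE`).
#' @return A [response_features()]; when no extremum qualifies, a
#'   no-response result with all fields `NA` and `detected = FALSE`.
#' @export
detect_response <- function(series, pos_band = c(5, 10),
                            neg_band = c(-10, -5),
                            baseline_correct = FALSE) {
  stopifnot(inherits(series, "eeg_series"))
  post <- post_stimulus(series)
  v <- post$values
  if (length(v) < 3L) stop("post-stimulus segment too short")
  if (baseline_correct) v <- v - mean(pre_stimulus(series)$values)

  ex <- local_extrema(v)
  qual <- ex[(ex$type == "max" & ex$value >= pos_band[1L]) |
             (ex$type == "min" & ex$value <= neg_band[2L]), ]
  if (nrow(qual) == 0L)
    return(response_features(detected = FALSE))

  rate <- post$sampling_rate
  lat <- function(i) (i - 1L) / rate   # latency of sample i post-stimulus
  first <- qual$index[1L]
  last <- qual$index[nrow(qual)]
  if (last == first) {
    # single qualifying peak: terminate at the deepest rebound after it
    after <- ex[ex$index > first & ex$type == "min", ]
    last <- if (nrow(after) > 0L) after$index[which.min(after$value)] else first
  }
  win <- v[first:last]
  p_idx <- qual$index[qual$type == "max"][1L]
  response_features(
    initiation_ms = lat(first) * 1000,
    duration_s = lat(last) - lat(first),
    peak_to_peak_uV = max(win) - min(win),
    p_time_s = if (length(p_idx) && is.finite(p_idx)) lat(p_idx) else NA_real_,
    n_time_s = if (last > first) lat(last) else NA_real_,
    detected = TRUE)
}

#' Grand average of stimulus-aligned trials
#'
#' Pointwise mean across trials. Background activity, being unlocked to
#' the stimulus, is suppressed roughly as 1/sqrt(n trials), while the
#' stimulus-locked response survives.
#'
#' @param trials A [trial_set()] or list of [eeg_series()] with identical
#'   geometry.
#' @return An [eeg_series()] with the shared sampling metadata.
#' @export
grand_average <- function(trials) {
  if (inherits(trials, "trial_set")) trials <- trials$trials
  if (inherits(trials, "eeg_series")) trials <- list(trials)
  trials <- trial_set(trials)$trials   # validates shared geometry
  tmpl <- trials[[1L]]
  vals <- rowMeans(vapply(trials, `[[`, numeric(length(tmpl$values)),
                          "values"))
  eeg_series(vals, tmpl$sampling_rate, t0 = tmpl$t0,
             stimulus_onset = tmpl$stimulus_onset)
}

#' Build a real-vs-predicted feature comparison table
#'
#' Takes paired lists of per-subject response features and lays them out
#' as one row per subject -- initiation time, duration and peak-to-peak
#' voltage, real next to predicted -- plus a final `Average` row holding
#' the arithmetic column means.
#'
#' @param real,predicted Lists of [response_features()], equal length.
#' @param labels Subject labels (default `"1"`, `"2"`, ...).
#' @return A data frame of class `response_comparison` with columns
#'   `subject`, `initiation_real_ms`, `initiation_pred_ms`,
#'   `duration_real_s`, `duration_pred_s`, `ptp_real_uV`, `ptp_pred_uV`.
#' @export
comparison_table <- function(real, predicted, labels = NULL) {
  if (inherits(real, "response_features")) real <- list(real)
  if (inherits(predicted, "response_features")) predicted <- list(predicted)
  if (length(real) != length(predicted) || length(real) == 0L)
    stop("'real' and 'predicted' must be non-empty paired lists")
  if (is.null(labels)) labels <- as.character(seq_along(real))
  get <- function(lst, f) vapply(lst, `[[`, numeric(1), f)
  out <- data.frame(
    subject = labels,
    initiation_real_ms = get(real, "initiation_ms"),
    initiation_pred_ms = get(predicted, "initiation_ms"),
    duration_real_s = get(real, "duration_s"),
    duration_pred_s = get(predicted, "duration_s"),
    ptp_real_uV = get(real, "peak_to_peak_uV"),
    ptp_pred_uV = get(predicted, "peak_to_peak_uV"),
    stringsAsFactors = FALSE)
  avg <- data.frame(subject = "Average",
                    t(colMeans(out[, -1L, drop = FALSE])),
                    stringsAsFactors = FALSE)
  names(avg) <- names(out)
  out <- rbind(out, avg)
  rownames(out) <- NULL
  class(out) <- c("response_comparison", "data.frame")
  out
}

#' Compare real and predicted sessions feature by feature
#'
#' For each paired subject, grand-averages the real and the predicted
#' trials, extracts the response features from each average, and builds
#' the comparison table (one row per subject plus the `Average` row).
#' Inputs that are already grand-averaged series are used as they are.
#'
#' @param real,predicted Paired lists of [trial_set()] (grand-averaged
#'   first) or of [eeg_series()] (used directly); a single set/series is
#'   treated as a one-subject list.
#' @param labels Subject labels.
#' @param ... Passed to [detect_response()].
#' @return A [comparison_table()] data frame.
#' @export
compare_features <- function(real, predicted, labels = NULL, ...) {
  as_series_list <- function(x) {
    if (inherits(x, c("trial_set", "eeg_series"))) x <- list(x)
    lapply(x, function(el) {
      if (inherits(el, "trial_set")) grand_average(el) else el
    })
  }
  real <- as_series_list(real)
  predicted <- as_series_list(predicted)
  if (length(real) != length(predicted))
    stop("'real' and 'predicted' must pair up subject by subject")
  comparison_table(lapply(real, detect_response, ...),
                   lapply(predicted, detect_response, ...),
                   labels = labels)
}

#' Side-by-side Hurst trajectories of real and predicted signals
#'
#' Applies [sliding_hurst()] identically to the post-stimulus segments of
#' the real and the predicted series and returns the two trajectories side
#' by side, for overlay plots or CSV export.
#'
#' @param real,predicted [eeg_series()] objects with stimulus markers and
#'   identical post-stimulus geometry.
#' @param window Window length in samples.
#' @param step Window step in samples (default 1).
#' @return A data frame with columns `time_s`, `H_real`, `H_predicted`.
#' @export
hurst_overlay <- function(real, predicted, window, step = 1L) {
  tr_r <- sliding_hurst(post_stimulus(real), window, step)
  tr_p <- sliding_hurst(post_stimulus(predicted), window, step)
  if (nrow(tr_r) != nrow(tr_p))
    stop("real and predicted post-stimulus segments differ in geometry")
  data.frame(time_s = tr_r$time_s, H_real = tr_r$H, H_predicted = tr_p$H)
}
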