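#' Evoked-response template
#'
#' The injected ground-truth response for synthetic trials: a positive
#' peak (P) followed by a negative rebound (N), each a Gaussian-shaped
#' bump at a stated post-stimulus latency. Default latencies and
#' amplitudes mirror the morphology of a typical visual evoked response
#' (P near 118 ms around +9 uV, N near 170 ms around -5 uV).
#'
#' @param p_latency P latency in seconds post-stimulus.
#' @param p_amplitude P amplitude in microvolts, > 0.
#' @param n_latency N latency in seconds post-stimulus, > `p_latency`.
#' @param n_amplitude N amplitude in microvolts, < 0.
#' @param width Bump standard deviation in seconds (default 0.015).
#' @return An object of class `evoked_template`.
#' @export
evoked_template <- function(p_latency = 0.118, p_amplitude = 9,
                            n_latency = 0.170, n_amplitude = -5,
                            width = 0.015) {
  if (p_latency >= n_latency) stop("'p_latency' must be < 'n_latency'")
  if (p_amplitude <= 0) stop("'p_amplitude' must be > 0")
  if (n_amplitude >= 0) stop("'n_amplitude' must be < 0")
  if (width <= 0) stop("'width' must be > 0")
  structure(list(p_latency = p_latency, p_amplitude = p_amplitude,
                 n_latency = n_latency, n_amplitude = n_amplitude,
                 width = width),
            class = "evoked_template")
}

#' Synthetic-trial specification
#'
#' The geometry and statistics of a synthetic EEG trial: one second of
#' pre-stimulus and one second of post-stimulus data at 256 Hz by default
#' (512 samples, stimulus at t = 1 s), with a fractional-Gaussian-noise
#' background of prescribed Hurst exponent and RMS amplitude and an
#' optional injected evoked template. Background defaults: H = 0.9 (the
#' strongly persistent regime typical of occipital EEG) and 2 uV RMS, so
#' that a +-5 uV response threshold separates response from background.
#'
#' @param sampling_rate Samples per second (default 256).
#' @param pre_s,post_s Pre-/post-stimulus durations in seconds (defaults
#'   1 and 1); each times `sampling_rate` must be an integer.
#' @param background_H Hurst exponent of the background in (0, 1).
#' @param background_scale Background RMS amplitude in microvolts.
#' @param evoked An [evoked_template()] or `NULL` for background only.
#' @param seed Integer seed, or `NULL` to draw from the current RNG.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(sampling_rate = 256, pre_s = 1, post_s = 1,
                       background_H = 0.9, background_scale = 2,
                       evoked = evoked_template(), seed = NULL) {
  if (sampling_rate <= 0) stop("'sampling_rate' must be > 0")
  n_pre <- pre_s * sampling_rate
  n_post <- post_s * sampling_rate
  if (abs(n_pre - round(n_pre)) > 1e-9 || abs(n_post - round(n_post)) > 1e-9)
    stop("pre_s * sampling_rate and post_s * sampling_rate must be integers")
  if (background_H <= 0 || background_H >= 1)
    stop("'background_H' must lie in (0, 1)")
  if (background_scale < 0) stop("'background_scale' must be >= 0")
  if (!is.null(evoked)) stopifnot(inherits(evoked, "evoked_template"))
  structure(list(sampling_rate = sampling_rate, pre_s = pre_s,
                 post_s = post_s, background_H = background_H,
                 background_scale = background_scale, evoked = evoked,
                 seed = seed),
            class = "trial_spec")
}

#' Simulate fractional Gaussian noise
#'
#' Exact-covariance fractional Gaussian noise (the stationary increments
#' of fractional Brownian motion) by circulant embedding: the fGn
#' autocovariance is embedded in a circulant matrix whose eigenvalues are
#' obtained by FFT, and a Gaussian vector with exactly that covariance is
#' synthesised spectrally. For H = 0.5 this reduces to white noise. If the
#' embedding is numerically indefinite (it is non-negative in exact
#' arithmetic for all H in (0, 1)), the generator falls back to a direct
#' Cholesky factorisation of the covariance matrix for n <= 4096 and
#' fails beyond that.
#'
#' @param n Number of samples, >= 2.
#' @param H Hurst exponent in (0, 1).
#' @param scale RMS amplitude in microvolts (the marginal standard
#'   deviation; default 1).
#' @param seed Integer seed for reproducibility, or `NULL` to use the
#'   current RNG stream.
#' @param sampling_rate Sampling rate attached to the returned series
#'   (default 256).
#' @return An [eeg_series()] of length `n` (t0 = 0, no stimulus marker).
#' @export
simulate_fgn <- function(n, H, scale = 1, seed = NULL, sampling_rate = 256) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be >= 2")
  if (!is.finite(H) || H <= 0 || H >= 1) stop("H must lie in (0, 1)")
  if (scale < 0) stop("'scale' must be >= 0")
  k <- 0:n
  acov <- scale^2 / 2 *
    (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  row <- c(acov[1:n], acov[n + 1L], acov[n:2])   # circulant first row, 2n
  lam <- Re(stats::fft(row))
  m <- 2L * n
  x <- if (min(lam) >= -1e-10 * max(abs(lam))) {
    lam[lam < 0] <- 0
    z <- with_seed(seed, stats::rnorm(2L * m))
    eps <- complex(real = z[1:m], imaginary = z[(m + 1L):(2L * m)])
    Re(stats::fft(sqrt(lam) * eps))[1:n] / sqrt(m)
  } else if (n <= 4096L) {
    covm <- outer(1:n, 1:n, function(i, j) acov[abs(i - j) + 1L])
    L <- chol(covm)
    drop(crossprod(L, with_seed(seed, stats::rnorm(n))))
  } else {
    stop("circulant embedding not positive semidefinite and n > 4096; ",
         "cannot generate exact-covariance fGn")
  }
  eeg_series(x, sampling_rate = sampling_rate, t0 = 0)
}

#' Generate one synthetic trial
#'
#' A background fGn record of `pre_s + post_s` seconds with the stimulus
#' marker at `pre_s`, plus the evoked template (two opposite-signed
#' Gaussian bumps at their stated latencies) added to the post-stimulus
#' segment when present.
#'
#' @param spec A [trial_spec()].
#' @return An [eeg_series()] with `stimulus_onset = spec$pre_s`.
#' @export
make_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  n <- round((spec$pre_s + spec$post_s) * spec$sampling_rate)
  bg <- if (spec$background_scale > 0)
    simulate_fgn(n, spec$background_H, spec$background_scale,
                 seed = spec$seed, sampling_rate = spec$sampling_rate)$values
  else numeric(n)
  t <- (seq_len(n) - 1L) / spec$sampling_rate
  v <- bg
  if (!is.null(spec$evoked)) {
    ev <- spec$evoked
    bump <- ev$p_amplitude *
      exp(-(t - (spec$pre_s + ev$p_latency))^2 / (2 * ev$width^2)) +
      ev$n_amplitude *
      exp(-(t - (spec$pre_s + ev$n_latency))^2 / (2 * ev$width^2))
    v <- v + bump * (t >= spec$pre_s)   # response is post-stimulus only
  }
  eeg_series(v, spec$sampling_rate, t0 = 0, stimulus_onset = spec$pre_s)
}

#' Generate a session of independent trials
#'
#' Draws `n_trials` independent trials from the same specification, with
#' per-trial seeds derived deterministically from the master seed, so a
#' session is reproducible as a whole.
#'
#' @param spec A [trial_spec()]; its `seed` is the master seed.
#' @param n_trials Number of trials, >= 1 (a recording session of 40
#'   artifact-free trials is the reference design).
#' @param subject_label Label carried on the set (default "synthetic").
#' @return An object of class `trial_set`: list with `trials` (list of
#'   [eeg_series()]) and `subject_label`.
#' @export
make_session <- function(spec, n_trials = 40L, subject_label = "synthetic") {
  stopifnot(inherits(spec, "trial_spec"))
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("'n_trials' must be >= 1")
  seeds <- with_seed(spec$seed,
                     sample.int(.Machine$integer.max - 1L, n_trials))
  trials <- lapply(seeds, function(s) {
    sp <- spec; sp$seed <- s
    make_trial(sp)
  })
  trial_set(trials, subject_label)
}

#' Bundle trials into a set
#'
#' @param trials List of [eeg_series()] with identical lengths, sampling
#'   rates and stimulus markers.
#' @param subject_label Label for the set.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(trials, subject_label = "synthetic") {
  if (!is.list(trials) || length(trials) < 1L)
    stop("'trials' must be a non-empty list")
  stopifnot(all(vapply(trials, inherits, logical(1), "eeg_series")))
  lens <- vapply(trials, function(s) length(s$values), integer(1))
  rates <- vapply(trials, `[[`, numeric(1), "sampling_rate")
  if (length(unique(lens)) != 1L || length(unique(rates)) != 1L)
    stop("all trials must share length and sampling_rate")
  onsets <- lapply(trials, `[[`, "stimulus_onset")
  if (length(unique(vapply(onsets, function(o) ifelse(is.null(o), NA_real_, o),
                           numeric(1)))) != 1L)
    stop("all trials must share the stimulus_onset")
  structure(list(trials = trials, subject_label = subject_label),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> '%s': %d trials x %d samples @ %g Hz\n",
              x$subject_label, length(x$trials), length(x$trials[[1L]]$values),
              x$trials[[1L]]$sampling_rate))
  invisible(x)
}
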