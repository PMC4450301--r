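# Build a quiet trial with Gaussian bumps at given latencies/amplitudes.
bump_trial <- function(rate, peaks, pre_s = 1, post_s = 1, width = 0.012) {
  n <- (pre_s + post_s) * rate
  t <- (seq_len(n) - 1) / rate
  v <- numeric(n)
  for (p in peaks)
    v <- v + p$amp * exp(-(t - (pre_s + p$lat))^2 / (2 * width^2))
  eeg_series(v, rate, t0 = 0, stimulus_onset = pre_s)
}

test_that("a reference-style P/N pair yields the printed feature values", {
  # +9 uV extremum at 118 ms and -4.97 uV at 170 ms post-stimulus on a
  # 1000 Hz grid; the rebound is below the 5 uV band edge yet terminates
  # the response
  tr <- bump_trial(1000, list(list(lat = 0.118, amp = 9),
                              list(lat = 0.170, amp = -4.97)))
  f <- detect_response(tr)
  expect_true(f$detected)
  expect_equal(f$initiation_ms, 118)
  expect_equal(f$duration_s, 0.052)
  expect_equal(f$peak_to_peak_uV, 13.97, tolerance = 1e-3)
})

test_that("quiet and sub-threshold signals yield a no-response result", {
  flat <- eeg_series(numeric(512), 256, stimulus_onset = 1)
  f <- detect_response(flat)
  expect_false(f$detected)
  expect_true(is.na(f$initiation_ms))
  small <- bump_trial(256, list(list(lat = 0.1, amp = 2),
                                list(lat = 0.2, amp = -2)))
  expect_false(detect_response(small)$detected)
})

test_that("a one-sample shift moves the initiation by one sample period", {
  peaks <- list(list(lat = round(0.118 * 256) / 256, amp = 9),
                list(lat = round(0.170 * 256) / 256, amp = -6))
  tr <- bump_trial(256, peaks)
  shifted <- eeg_series(c(tr$values[1], tr$values[-length(tr$values)]),
                        256, t0 = 0, stimulus_onset = 1)
  f0 <- detect_response(tr)
  f1 <- detect_response(shifted)
  expect_equal(f1$initiation_ms - f0$initiation_ms, 1000 / 256)
})

test_that("bands are absolute unless baseline correction is requested", {
  peaks <- list(list(lat = 0.12, amp = 6), list(lat = 0.18, amp = -6))
  tr <- bump_trial(256, peaks)
  offset <- eeg_series(tr$values - 3, 256, t0 = 0, stimulus_onset = 1)
  f_raw <- detect_response(offset)
  f_corr <- detect_response(offset, baseline_correct = TRUE)
  ref <- detect_response(tr)
  # the offset pushes the positive peak below the band edge
  expect_false(isTRUE(all.equal(f_raw$peak_to_peak_uV, ref$peak_to_peak_uV)))
  expect_equal(f_corr$initiation_ms, ref$initiation_ms)
  expect_equal(f_corr$peak_to_peak_uV, ref$peak_to_peak_uV, tolerance = 1e-9)
})

test_that("grand averaging is the pointwise mean and is linear", {
  set.seed(2)
  a <- eeg_series(rnorm(128), 256, stimulus_onset = 0.25)
  b <- eeg_series(rnorm(128), 256, stimulus_onset = 0.25)
  neg <- eeg_series(-a$values, 256, stimulus_onset = 0.25)
  expect_equal(grand_average(list(a, a, a))$values, a$values)
  expect_equal(grand_average(list(a, neg))$values, numeric(128))
  ga <- grand_average(list(a, b))
  expect_equal(ga$values, (a$values + b$values) / 2)
  expect_equal(ga$stimulus_onset, 0.25)
  short <- eeg_series(rnorm(64), 256)
  expect_error(grand_average(list(a, short)), "share")
})

test_that("the comparison table appends an exact arithmetic average row", {
  rows <- reference_feature_rows()
  tab <- comparison_table(rows$real, rows$predicted)
  expect_equal(nrow(tab), 7)
  expect_equal(tab$subject[7], "Average")
  for (col in names(tab)[-1])
    expect_equal(tab[[col]][7], mean(tab[[col]][1:6]))
  # one pair: the average row equals the single row
  one <- comparison_table(rows$real[1], rows$predicted[1])
  expect_equal(unlist(one[2, -1]), unlist(one[1, -1]))
})

test_that("recomputed averages agree with the reference table to printed precision", {
  rows <- reference_feature_rows()
  tab <- comparison_table(rows$real, rows$predicted)
  avg <- tab[tab$subject == "Average", ]
  printed <- c(initiation_real_ms = 113, initiation_pred_ms = 123,
               duration_real_s = 0.055, duration_pred_s = 0.052,
               ptp_real_uV = 14.11, ptp_pred_uV = 14.14)
  ulp <- c(1, 1, 0.001, 0.001, 0.01, 0.01)   # one unit of last printed digit
  for (i in seq_along(printed))
    expect_lt(abs(avg[[names(printed)[i]]] - printed[i]), ulp[i])
})

test_that("identical sessions compare as equal columns", {
  set <- make_session(trial_spec(seed = 12), n_trials = 5)
  tab <- compare_features(list(set), list(set))
  expect_equal(tab$initiation_real_ms, tab$initiation_pred_ms)
  expect_equal(tab$ptp_real_uV, tab$ptp_pred_uV)
  expect_error(compare_features(list(set), list(set, set)), "pair")
})

test_that("hurst overlays run the same estimator on both signals", {
  real <- eeg_series(simulate_fgn(1280, 0.9, seed = 41)$values, 256,
                     stimulus_onset = 1)
  pred_same <- real
  ov <- hurst_overlay(real, pred_same, window = 256, step = 32)
  expect_equal(ov$H_real, ov$H_predicted)
  pred2 <- eeg_series(simulate_fgn(1280, 0.9, seed = 42)$values, 256,
                      stimulus_onset = 1)
  ov2 <- hurst_overlay(real, pred2, window = 256, step = 32)
  expect_lt(abs(mean(ov2$H_real) - 0.9), 0.12)
  expect_lt(abs(mean(ov2$H_predicted) - 0.9), 0.12)
  flat <- eeg_series(rep(1, 1280), 256, stimulus_onset = 1)
  expect_error(hurst_overlay(real, flat, window = 256), "degenerate")
})
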