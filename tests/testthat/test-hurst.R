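test_that("R/S estimate of white noise is near 0.5", {
  set.seed(42)
  est <- rs_hurst(rnorm(8192))
  expect_s3_class(est, "hurst_estimate")
  expect_lt(abs(est$H - 0.5), 0.1)
  expect_gte(est$n_scales, 3)
})

test_that("R/S recovers the Hurst exponent of exact-covariance fGn", {
  for (H in c(0.7, 0.8)) {
    est <- vapply(1:8, function(s)
      rs_hurst(simulate_fgn(8192, H, seed = 1000 + s))$H, numeric(1))
    expect_lt(abs(mean(est) - H), 0.1)
  }
})

test_that("R/S is exactly invariant under positive affine transforms", {
  set.seed(7)
  x <- cumsum(rnorm(1024))
  h1 <- rs_hurst(x)
  h2 <- rs_hurst(3.7 * x - 42)
  expect_equal(h1$raw_slope, h2$raw_slope, tolerance = 1e-12)
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(rs_hurst(rep(5, 1024)), "degenerate")
  expect_error(rs_hurst(rnorm(10)), "too short")
})

test_that("clamping keeps H in [0, 1] while preserving the raw slope", {
  # a strong deterministic trend pushes the raw R/S slope above 1
  est <- rs_hurst((1:512)^2 + sin(1:512) * 1e-6)
  expect_gte(est$H, 0)
  expect_lte(est$H, 1)
  expect_true(is.finite(est$raw_slope))
})

test_that("reflection maps H into [0.5, 1] and is idempotent", {
  expect_equal(reflect_h(0.2), 0.8)
  expect_equal(reflect_h(0.5), 0.5)
  expect_equal(reflect_h(0.75), 0.75)
  H <- seq(0, 1, by = 0.01)
  r <- reflect_h(H)
  expect_true(all(r >= 0.5 & r <= 1))
  expect_equal(reflect_h(r), r)
  expect_error(reflect_h(1.2), "0, 1")
})

test_that("trend direction follows persistence and flips under antipersistence", {
  expect_equal(trend_direction(0.8, +1), +1)
  expect_equal(trend_direction(0.8, -1), -1)
  expect_equal(trend_direction(0.3, +1), -1)
  expect_equal(trend_direction(0.3, -1), +1)
  # H = 0.5: a fair coin, reproducible under a seed
  d1 <- trend_direction(0.5, +1, seed = 99)
  d2 <- trend_direction(0.5, +1, seed = 99)
  expect_equal(d1, d2)
  expect_true(d1 %in% c(-1, 1))
  # both outcomes occur over seeds
  ds <- vapply(1:40, function(s) trend_direction(0.5, +1, seed = s), numeric(1))
  expect_setequal(unique(ds), c(-1, 1))
  expect_error(trend_direction(0.7, 0), "\\+1 or -1")
})

test_that("sliding windows produce one trailing-edge estimate per position", {
  set.seed(3)
  s <- eeg_series(rnorm(512), sampling_rate = 256)
  tr <- sliding_hurst(s, window_length = 256, step = 1)
  expect_equal(nrow(tr), 257)
  expect_true(all(tr$H >= 0.3 & tr$H <= 0.7))
  # trailing edge: first estimate is stamped at the 256th sample's time
  expect_equal(tr$time_s[1], 255 / 256)
  expect_equal(tr$time_s[257], 511 / 256)

  one <- sliding_hurst(eeg_series(rnorm(256), 256), window_length = 256)
  expect_equal(nrow(one), 1)
})

test_that("sliding windows track strongly persistent fGn", {
  s <- simulate_fgn(2048, 0.9, seed = 17)
  tr <- sliding_hurst(s, window_length = 512, step = 64)
  expect_lt(abs(mean(tr$H) - 0.9), 0.1)
})

test_that("trajectory variance shrinks as the window grows", {
  vars <- sapply(c(64, 256), function(w) {
    mean(vapply(1:5, function(s) {
      tr <- sliding_hurst(simulate_fgn(1024, 0.7, seed = 500 + s),
                          window_length = w, step = 32)
      var(tr$H)
    }, numeric(1)))
  })
  expect_lt(vars[2], vars[1])
})

test_that("windows below twice the minimum scale are rejected", {
  expect_error(sliding_hurst(eeg_series(rnorm(256), 256), window_length = 12),
               "2 \\* min_window")
  expect_error(sliding_hurst(eeg_series(rnorm(128), 256), window_length = 256),
               "exceeds")
})
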