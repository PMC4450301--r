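test_that("the Gaussian pulse follows the model's exponent convention", {
  p <- stimulus_pulse(phi0 = 1, t_star = 0.002, sigma = 0.001)
  expect_equal(gaussian_flux(p$t_star, p), 1)
  expect_equal(gaussian_flux(p$t_star + p$sigma, p), exp(-1))
  expect_equal(gaussian_flux(0.004, p), exp(-4))   # reference parameter set
  # conventional variant restores the 2 sigma^2 denominator
  expect_equal(gaussian_flux(p$t_star + p$sigma, p, "conventional"),
               exp(-0.5))
  expect_error(stimulus_pulse(sigma = 0), "positive")
})

test_that("pulse trains superpose linearly", {
  p <- stimulus_pulse()
  t <- seq(0, 0.01, by = 1e-4)
  expect_equal(pulse_train_flux(t, list(p)), gaussian_flux(t, p))
  expect_equal(pulse_train_flux(t, list(p, p)), 2 * gaussian_flux(t, p))
  # widely separated pulses barely interact at each other's peak
  q <- stimulus_pulse(t_star = 0.5)
  dev <- abs(pulse_train_flux(p$t_star, list(p, q)) - p$phi0)
  expect_lt(dev, exp(-((q$t_star - p$t_star) / p$sigma)^2) + 1e-15)
  expect_error(pulse_train_flux(0, list()), "non-empty")
})

test_that("the fractional integral of constant flux is exact", {
  fl <- flux_series(c(0, 1), c(1, 1))
  for (H in c(0.3, 0.5, 0.8, 1)) {
    expect_equal(frac_integral(fl, H, 0.8), 0.8^H / gamma(H + 1),
                 tolerance = 1e-14)
  }
  zero <- flux_series(c(0, 1), c(0, 0))
  expect_equal(frac_integral(zero, 0.7, 0.5), 0)
  expect_equal(frac_integral(fl, 0.7, 0), 0)
  expect_error(frac_integral(fl, 1.5, 0.5), "\\(0, 1\\]")
  expect_error(frac_integral(fl, 0.7, 2), "beyond the flux support")
})

test_that("product integration matches the adaptive-quadrature oracle", {
  p <- stimulus_pulse()
  for (H in c(0.5, 0.7, 1.0)) {
    for (t in c(0.01, 0.1)) {
      fl <- pulse_flux_series(p, t_end = t, fine_per_sigma = 200)
      expect_equal(frac_integral(fl, H, t), quad_frac_integral(p, H, t),
                   tolerance = 1e-6)
    }
  }
})

test_that("product-integration error decays at the piecewise-linear rate", {
  p <- stimulus_pulse()
  H <- 0.7; t <- 0.05
  truth <- quad_frac_integral(p, H, t)
  err <- vapply(c(2.5e-4, 1.25e-4), function(dt) {
    g <- unique(c(seq(0, t, by = dt), t))
    fl <- flux_series(g, gaussian_flux(g, p))
    abs(frac_integral(fl, H, t) - truth)
  }, numeric(1))
  order <- log2(err[1] / err[2])
  expect_gte(order, 1.5)
})

test_that("zero flux returns the baseline and scaling is linear", {
  zero <- flux_series(c(0, 1), c(0, 0))
  expect_equal(fractional_response(zero, 0.8, 1e-4, 1e-3, V0 = 3.2, t = 0.5),
               3.2)
  p <- stimulus_pulse()
  fl1 <- pulse_flux_series(p, 0.5)
  fl3 <- flux_series(fl1$times, 3 * fl1$flux)
  v1 <- fractional_response(fl1, 0.8, 1e-4, 1e-3, 0, 0.5)
  v3 <- fractional_response(fl3, 0.8, 1e-4, 1e-3, 0, 0.5)
  expect_equal(v3, 3 * v1, tolerance = 1e-12)
})

test_that("constant flux at H = 1/2 reproduces random-walk growth", {
  # closed form: V0 + 2 phi0 sqrt(t) / (sqrt(pi) sqrt(D_eff)); tau drops out
  fl <- flux_series(c(0, 2), c(1, 1))
  D_eff <- 6.5e-4
  for (tau in c(1e-3, 0.3)) {
    expect_equal(fractional_response(fl, 0.5, D_eff, tau, V0 = 1, t = 1.5),
                 1 + 2 * sqrt(1.5) / (sqrt(pi) * sqrt(D_eff)),
                 tolerance = 1e-12)
  }
  # literal variant divides by D_eff instead of sqrt(D_eff)
  d <- fractional_response(fl, 0.8, D_eff, 1e-3, 0, 1)
  l <- fractional_response(fl, 0.8, D_eff, 1e-3, 0, 1, variant = "literal")
  expect_equal(l / d, 1 / sqrt(D_eff), tolerance = 1e-12)
  expect_error(fractional_response(fl, 0.8, 0, 1e-3, 0, 1), "positive")
})

test_that("the growth exponent equals H across the diffusion-wave range", {
  for (H in c(0.5, 0.8, 1.0))
    expect_lt(abs(growth_exponent(H) - H), 1e-6)
})

test_that("the response is causal in the flux history", {
  p <- stimulus_pulse()
  fl <- pulse_flux_series(p, 0.5)
  t_obs <- 0.2
  before <- frac_integral(fl, 0.7, t_obs)
  tampered <- fl
  tampered$flux[tampered$times > t_obs] <-
    tampered$flux[tampered$times > t_obs] + 100
  expect_equal(frac_integral(tampered, 0.7, t_obs), before, tolerance = 1e-12)
})

test_that("a zero-amplitude pulse predicts a flat record at V0", {
  prestim <- simulate_fgn(257, 0.9, 2, seed = 5)
  prestim <- eeg_series(prestim$values, 256, t0 = 0, stimulus_onset = 1)
  cfg <- model_config(pulse = stimulus_pulse(phi0 = 0),
                      h_policy = "fixed", H_fixed = 0.8)
  pred <- predict_signal(prestim, cfg, duration = 0.25)
  V0 <- prestim$values[257]
  expect_equal(pred$series$values, rep(V0, length(pred$series$values)))
  expect_equal(pred$series$values[1], V0)
})

test_that("the fixed-H loop agrees with a direct single-call evaluation", {
  prestim <- simulate_fgn(257, 0.9, 2, seed = 11)
  prestim <- eeg_series(prestim$values, 256, t0 = 0, stimulus_onset = 1)
  cfg <- model_config(h_policy = "fixed", H_fixed = 0.8, dt = 1 / 256)
  pred <- predict_signal(prestim, cfg, duration = 1)
  vals <- pred$series$values
  expect_equal(length(vals), 257)
  expect_true(all(is.finite(vals)))
  k <- which.max(vals) - 1L
  t_k <- k / 256
  fl <- pulse_flux_series(stimulus_pulse(), t_end = 1, fine_per_sigma = 50,
                          coarse_dt = max(1 / 512, 1 / 4000))
  D_k <- effective_diffusivity(t_k, 0.8, tissue_params())
  direct <- fractional_response(fl, 0.8, D_k, 1e-3, vals[1], t_k)
  expect_equal(max(vals), direct, tolerance = 1e-9)
})

test_that("a persistent background yields one dominant positive deflection", {
  prestim <- simulate_fgn(257, 0.9, 2, seed = 21)
  prestim <- eeg_series(prestim$values, 256, t0 = 0, stimulus_onset = 1)
  cfg <- model_config(h_policy = "trailing", seed = 1)
  pred <- predict_signal(prestim, cfg, duration = 1)
  dev <- pred$series$values - pred$series$values[1]
  expect_gt(max(dev), 5)                 # response exceeds the 5 uV band
  expect_gt(max(dev), -min(dev))         # and is dominantly positive
  expect_true(all(pred$H_trajectory$H >= 0 & pred$H_trajectory$H <= 1))
  expect_true(all(pred$D_eff_trajectory$D_eff_m2s >= 0))
})

test_that("antipersistent moments flip the deflection direction", {
  # fixed H below 0.5 alternates the trend at every step
  prestim <- eeg_series(sin(1:257 / 3), 256, t0 = 0, stimulus_onset = 1)
  cfg <- model_config(h_policy = "fixed", H_fixed = 0.3)
  pred <- predict_signal(prestim, cfg, duration = 0.1)
  incr <- diff(pred$series$values)
  signs <- sign(incr[incr != 0])
  expect_true(length(signs) > 2 && all(signs[-1] != signs[-length(signs)]))
})
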