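# fdeeg — fractional-diffusion modelling of evoked EEG responses

`fdeeg` is an R package for modelling and predicting the single-channel
EEG response to an external stimulus under a fractional-diffusion view of
the signal: the voltage record is treated as a fractal time series whose
Hurst exponent H sets both the *direction* of the next deflection
(persistent for H > 1/2, antipersistent for H < 1/2) and, through a
fractional diffusion equation of temporal order 2H, its *magnitude*. It
is written for researchers who work with stimulus-locked EEG (evoked /
event-related potentials) and want a compact, fully reproducible
implementation of this model family together with the estimation and
evaluation machinery around it.

The core model: the response to a stimulus flux φ(t) is the
Riemann–Liouville fractional integral

    V(t) = V0 + C^(2H−1) D_eff^(−H) · 1/Γ(H) · ∫₀ᵗ φ(ξ) (t−ξ)^(H−1) dξ,

with the stimulus modelled as a Gaussian flux pulse
φ(t) = φ₀·exp[−(t−t\*)²/σ²] and the *time-dependent* effective
diffusivity of neural tissue given by the phase-lagging/Bessel law

    D_eff/D = [ 2^(1−H) Γ(H) z^(1−H) I₀(z) e^(−z) ]²,   z = t/2τ,

where τ is the tissue relaxation time and I₀ the zero-order modified
Bessel function (evaluated in exponentially scaled form). The package
provides:

* **`rs_hurst()` / `sliding_hurst()`** — classical rescaled-range (R/S)
  Hurst estimation and its time-resolved, trailing-edge-stamped variant;
  `reflect_h()` and `trend_direction()` implement the reflection rule
  H′ = 1 − H and the persistence/antipersistence direction logic.
* **`dimensionless_diffusivity()` / `effective_diffusivity()` /
  `propagation_speed()`** — the diffusivity law, its large-z asymptote
  (`asymptotic_ratio()`) and the τ = D_eff/C² relation.
* **`frac_integral()` / `fractional_response()` / `predict_signal()`** —
  singularity-exact product integration of the fractional integral and
  the per-moment prediction loop.
* **`simulate_fgn()` / `make_trial()` / `make_session()`** — seedable
  synthetic EEG trials: exact-covariance fractional Gaussian noise
  background plus an injectable P/N evoked template.
* **`detect_response()` / `grand_average()` / `compare_features()`** —
  evoked-feature extraction (initiation latency, duration, peak-to-peak
  voltage) and real-vs-predicted comparison tables.
* **`read_signal()` / `write_signal()` / `bandpass()` /
  `wavelet_denoise()`** — plain-text signal I/O and standard EEG
  preprocessing.
* A command line (`exec/fdeeg`, or `fdeeg_cli()` from R) with
  `simulate`, `predict`, `hurst`, `diffusivity`, `features` and
  `compare` subcommands; every run logs its fully resolved configuration
  and seed.

## Worked example

Simulate a 40-trial session, grand-average it, and extract the evoked
features; then predict a post-stimulus second from a pre-stimulus record:

```r
library(fdeeg)

spec    <- trial_spec(seed = 2024)           # 256 Hz, 1 s + 1 s, H = 0.9 background
session <- make_session(spec, n_trials = 40)
ga      <- grand_average(session)
ga
#> <eeg_series> 512 samples @ 256 Hz, t = [0, 1.99609] s, stimulus at 1 s

detect_response(ga)
#> <response_features> P at 117.2 ms, duration 0.051 s, peak-to-peak 13.98 uV

rs_hurst(pre_stimulus(ga))
#> <hurst_estimate> H = 0.8788 (raw slope 0.8788 +/- 0.0319, 10 scales)

dimensionless_diffusivity(c(0.5, 1, 10, 1e6), 0.5)
#> [1] 1.307124 1.363024 1.026758 1.000000

prestim <- eeg_series(simulate_fgn(257, 0.9, 2, seed = 11)$values,
                      sampling_rate = 256, t0 = 0, stimulus_onset = 1)
pred <- predict_signal(prestim,
                       model_config(h_policy = "fixed", H_fixed = 0.9),
                       duration = 1)
round(max(pred$series$values - pred$series$values[1]), 2)
#> [1] 27.04
```

Reading the numbers: the injected template (P +9 µV at 118 ms, N −5 µV at
170 ms) is recovered on the 256 Hz grid — 117.2 ms is the nearest sample
to 118 ms, and 13.98 µV ≈ the injected 14 µV peak-to-peak after 40-trial
averaging suppresses the 2 µV background ~6-fold. The pre-stimulus Hurst
estimate 0.88 recovers the generator's H = 0.9 within the estimator's
spread. The diffusivity ratio at H = 1/2 rises through a maximum (≈1.36
near z ≈ 0.8) before settling at its limit 1. The predicted deflection
magnitude (here ≈27 µV) scales with the configured τ and
flux-to-microvolt conversion; see the vignette on why only shape-level
statements are parameter-free.

The same pipeline from the shell:

```sh
Rscript exec/fdeeg simulate --seed 7 --n-trials 40 --out trials/
Rscript exec/fdeeg predict  --input trials/trial_001.txt --onset 1 --tau 0.001
Rscript exec/fdeeg features --input trials/trial_001.txt --onset 1 --out features.csv
```

`predict` requires `--tau` explicitly: the relaxation time has no
canonical published value, so the CLI refuses to default it.

## Package layout

```
R/             implementation (hurst, diffusivity, response model,
               synthetic trials, features, io, cli)
tests/testthat unit, property and acceptance-level tests
scripts/       acceptance script
vignettes/     methods vignette (model, conventions, limitations)
exec/          command-line wrapper
```
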