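---
title: "Modelling evoked EEG responses with fractional diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling evoked EEG responses with fractional diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdeeg)
```

## The model

`fdeeg` treats a single-channel EEG record as a fractal time series: a
transient record of a random-walk-like process whose scaling exponent — the
Hurst exponent H in [0, 1] — measures how predictable the next deflection
is. H = 1/2 is an uncorrelated random walk, H > 1/2 a persistent process
(the next deflection tends to continue the previous trend), H < 1/2 an
antipersistent one (it tends to reverse it). Under this reading the voltage
V obeys a diffusion equation of *fractional temporal order 2H*, which
interpolates between the Poisson equation (H = 0), classical diffusion
(H = 1/2) and the wave equation (H = 1). The spatial coordinate is an
abstract "informational distance" between neurons; it never appears in the
computed solution because, after applying Fick's law, the solution is
driven entirely by the flux history at the observation site:

$$ V(t) \;=\; V_0 \;+\; C^{2H-1} D_\mathrm{eff}^{-H}\,
   \frac{1}{\Gamma(H)} \int_0^t \frac{\varphi(\xi)}{(t-\xi)^{1-H}}\,d\xi $$

— a Riemann–Liouville fractional integral of order H of the flux
$\varphi$, with a weakly singular kernel. The external stimulus is modelled
as a Gaussian flux pulse
$\varphi(t) = \varphi_0 \exp\!\left[-(t-t^*)^2/\sigma^2\right]$. Note the
exponent: the model's pulse is defined *without* the factor 2 that a
Gaussian density with standard deviation $\sigma$ would carry. We evaluate
it exactly in that form by default and expose
`exponent = "conventional"` for the $2\sigma^2$ form, so the discrepancy is
visible rather than silently corrected.

Three physical constants parameterise the tissue: the diffusivity
D (default 6.5e-4 m²/s, the model's reference value), the relaxation time
$\tau$ — the finite lag between stimulus and response, tied to the impulse
propagation speed by $\tau = D_\mathrm{eff}/C^2$ — and the stimulus
parameters $(\varphi_0, t^*, \sigma)$ = (1 V·m/s, 0.002 s, 0.001 s).
**$\tau$ has no published reference value.** The library default is
$\tau$ = 0.001 s, the same order as the stimulus width; it is printed in
every resolved-configuration log, and the command-line `predict`
subcommand deliberately refuses to run without an explicit `--tau`, so no
analysis can depend on the default silently.

## The effective diffusivity law

Equating the fractional-diffusion solution with the phase-lagging model of
the action potential yields a *time-dependent* effective diffusivity. With
the dimensionless time $z = t/2\tau$:

$$ \frac{D_\mathrm{eff}}{D} \;=\;
   \left[\, 2^{1-H}\,\Gamma(H)\, z^{1-H}\, I_0(z)\, e^{-z} \right]^2 , $$

where $I_0$ is the zero-order modified Bessel function. The square on the
bracket is adopted because it is the only reading consistent with the
law's own limits, which we verify in the test suite: substituting the
large-z asymptote $I_0(z) \sim e^z/\sqrt{2\pi z}$ gives the power law
$2^{1-2H}\Gamma^2(H)\,\pi^{-1} z^{1-2H}$, hence exactly 1 at H = 1/2 and
decay to 0 for H > 1/2. The unsquared variant (available via
`squared = FALSE`) satisfies neither limit.

Two numerical points:

* $I_0(z)$ overflows double precision near z = 700, so the implementation
  always works with the exponentially scaled product $I_0(z)e^{-z}$. R's
  `besselI(..., expon.scaled = TRUE)` itself underflows to zero for
  z beyond roughly 7e5, so above z = 500 we switch to the standard
  five-term asymptotic series for the scaled function; the two branches
  agree to about 1e-13 at the switch point (tested).
* The curve is *unimodal*, not monotone: for every H it rises from 0
  (from 1 when H = 1, where the z-power vanishes) to a single interior
  maximum — about 1.38 near z ≈ 0.8 for H = 1/2 — and then decays to its
  limit (1 for H = 1/2, 0 for H > 1/2). The tests assert exactly this
  shape: at most one sign change of the finite differences, a decaying
  tail, and the two limits.

```{r diffusivity, eval = FALSE}
curve_05 <- diffusivity_curve(0.5, z = seq(0.05, 30, length.out = 400))
curve_09 <- diffusivity_curve(0.9, z = seq(0.05, 30, length.out = 400))
plot(curve_05, type = "l", xlab = "z = t / 2 tau", ylab = "D_eff / D")
lines(curve_09, lty = 2)
```

Since only the span H in [0.5, 1] is needed — an exponent H below 1/2
describes the same fluctuation magnitude as its mirror image 1 − H —
magnitude computations reflect H via `reflect_h()` first; the unreflected
value still decides the *direction* of the next deflection through
`trend_direction()`. At exactly H = 1/2 the direction is a seeded fair
coin flip: the process has no correlation there, and any deterministic
tie-break would bias the random-walk case.

## Estimating H: rescaled-range analysis

`rs_hurst()` implements classical R/S analysis: cut the series into
non-overlapping segments of length w, compute within each segment the
range of the mean-adjusted cumulative sum divided by the segment standard
deviation, average across segments, repeat over a geometric schedule of
w, and take the OLS slope of log2(R/S) against log2(w). Defaults: 10
scales between w = 16 and w = n/2, mean-adjustment only (a linear
within-segment detrend is available as `detrend = "linear"`).

The minimum scale of 16 is a deliberate bias control. The expected R/S of
very short segments deviates substantially from its asymptotic power law,
which tilts the regression upward: with the minimum at 8 the estimator
averages about 0.547 on white noise of length 8192, while at 16 it
averages about 0.535 with fGn recovery across H = 0.6–0.9 also improving.
Because the raw slope can still leave [0, 1] on short or trended windows,
the reported `H` is clamped to the model's admissible range and the raw
slope is kept in the estimate.

`sliding_hurst()` tracks H in time. Each window's estimate is stamped at
the window's *trailing edge*, so the trajectory at time t uses only data
up to t — the convention the predictor needs. The default window is one
second of samples (256 at the reference rate), matching the rule that the
initial H comes from the full pre-stimulus second.

## The per-moment prediction loop

`predict_signal()` steps the model clock from the stimulus onset in
increments of `dt` (default 1/256 s). At each step k it:

1. obtains $H_k$ per the `h_policy` — `"trailing"` (default): R/S over
   the trailing one-second window of the concatenated pre-stimulus +
   predicted-so-far record, i.e. free-running; `"prestim"`: constant,
   from the pre-stimulus second; `"fixed"`: a given value;
2. reflects $H_k$ into [0.5, 1] for the magnitude model;
3. evaluates $D_{\mathrm{eff},k}$ at $t_k$;
4. evaluates the fractional-integral response to the *full* flux history
   under a frozen-coefficient (quasi-static) convention: the current
   $H_k$ and $D_{\mathrm{eff},k}$ parameterise the whole integral. A
   time-varying order inside a convolution is mathematically
   under-defined; freezing the coefficients at their current values is
   the simplest convention consistent with a per-moment update, and it
   makes the fixed-H loop agree exactly with a direct single-call
   evaluation (tested to 1e-9);
5. composes the output sample as
   $V_k = V_{k-1} + s_k\,\lvert \Delta V_k\rvert$, where
   $\lvert\Delta V_k\rvert$ is the magnitude-model increment and the sign
   $s_k$ comes from `trend_direction()` applied to the unreflected $H_k$.

The sign/magnitude composition is a policy, and it has a visible
consequence worth stating plainly: while H stays persistent the direction
never flips, so the predicted record is monotone in each run of constant
trend — a negative rebound can only arise from antipersistent moments
(H < 0.5) or the H = 1/2 coin flip. A recorded evoked response owes its
P-then-N shape to H dipping at the rebound; a synthetic strongly
persistent background produces the dominant positive deflection but not,
by itself, the rebound. The tests assert exactly what the model can do:
the dominant deflection under persistence and strict alternation under
antipersistence.

Two further conventions: the model clock t = 0 maps to the recording's
stimulus-onset time (1 s in the reference trial geometry), and a single
configured factor (default 1) converts the flux units to microvolts,
since the model's voltage scale is otherwise unspecified.

## Evaluating the singular integral

`frac_integral()` uses product integration: the flux is taken piecewise
linear between its samples and the kernel moments
$\int (t-\xi)^{H-1} d\xi$ and $\int \xi\,(t-\xi)^{H-1} d\xi$ are
integrated *exactly* on every sub-interval, so the integrable singularity
at $\xi = t$ contributes analytically. The scheme is exact for
piecewise-linear flux — constant flux gives $t^H/\Gamma(H{+}1)$ to
round-off, which is why `growth_exponent()` recovers H to 1e-6 and the
classical $t^{1/2}$ and wave-like $t^{1}$ growth laws fall out exactly —
and its only error is the linear-interpolation error of the sampled flux,
observed to converge at second order (tested ≥ 1.5). Because the default
pulse (σ = 1 ms) is narrower than one 256 Hz sample, `pulse_flux_series()`
samples the flux on a grid that is dense across the pulse support
(σ/50 by default) and coarse elsewhere; against an adaptive-quadrature
oracle with the singularity removed by substitution, the scheme agrees to
better than 1e-6 relative across H in [0.5, 1] and t up to 0.5 s.

## Synthetic trials

No EEG recordings are distributed, so `make_session()` generates the test
substrate: trials of 1 s pre- plus 1 s post-stimulus at 256 Hz
(512 samples, stimulus at t = 1 s), with

* a fractional Gaussian noise background from `simulate_fgn()` —
  exact-covariance circulant embedding, deterministic under a seed, with
  a Cholesky fallback for numerically indefinite embeddings. Defaults:
  H = 0.9 (occipital EEG in this framework is strongly persistent, with
  per-subject H roughly 0.90–0.95) and 2 µV RMS, chosen so a ±5 µV
  response threshold separates response from background;
* an optional evoked template: Gaussian bumps of width 0.015 s, a
  positive peak +9 µV at 118 ms and a negative rebound −5 µV at 170 ms —
  latencies and amplitudes that mirror typical visual evoked responses.
  The bump shape is the package's own choice; only peak latencies and
  amplitudes have reference values.

What the generator deliberately does *not* emulate: multichannel head
geometry, ocular/muscle artifacts, trial-to-trial latency jitter, alpha
rhythms, non-stationary background H. Passing tests therefore show that
the pipeline recovers what it injects under the model's own assumptions —
not that recorded EEG satisfies those assumptions.

## Feature extraction

`detect_response()` screens local extrema of the post-stimulus segment
against the response bands (5 to 10 µV and −5 to −10 µV). Magnitudes
beyond a band's far edge also qualify — observed peak-to-peak values
exceed 16 µV, so the bands cannot be exclusive. The initiation time is
the latency of the first qualifying peak; the response ends at the last
qualifying peak; when only one peak qualifies, the terminating negative
rebound is taken as the deepest negative extremum after the first peak,
whatever its depth (reference responses terminate at rebounds as shallow
as −4.97 µV). Peak-to-peak voltage is max − min over the enclosed window.
Bands are absolute voltages; `baseline_correct = TRUE` subtracts the
pre-stimulus mean first. Latencies are reported on the sample grid
(1000/256 ≈ 3.9 ms resolution at the reference rate).

`grand_average()` is the pointwise mean of stimulus-aligned trials, and
`compare_features()` grand-averages each subject's real and predicted
sets first and then extracts features — averaging-first is the default
order; extract-then-average can be composed manually from
`detect_response()` over trials.

## Numerical choices and degenerate inputs

* Constant series have undefined R/S: a degenerate-input error, not NaN.
  Zero-variance segments within a window are skipped; scales with no
  usable segment are dropped; fewer than 3 usable scales is an error.
* `frac_integral()` refuses to extrapolate beyond the flux support.
* Preprocessing: zero-phase 4th-order Butterworth bandpass
  (0.1–70 Hz default) with odd-reflection padding; wavelet denoising by
  periodised db4 DWT, 4 levels, universal soft threshold with the noise
  level estimated from the finest detail coefficients (MAD/0.6745). The
  DWT is implemented in-package and pinned by perfect-reconstruction and
  energy-conservation tests.
* Problem sizes in the test suite — n = 8192 with 20 seeds for estimator
  recovery, 40-trial sessions for the pipeline checks, 2000-point z-grids
  for curve-shape checks — are chosen so every stochastic assertion sits
  several standard errors inside its tolerance while the whole suite runs
  in well under a minute.

## Known limitations

* The relaxation time τ and the flux-to-microvolt conversion are free
  parameters; predictions scale with them, and only dimensionless or
  shape-level statements are parameter-free.
* The frozen-coefficient convention is one of several defensible readings
  of a time-varying H inside a convolution; a step-local (memoryless)
  update would differ. The policy objects keep the alternatives swappable.
* The sign/magnitude composition cannot produce a rebound while H stays
  persistent (see above); this is a property of the model as specified,
  not of the implementation.
* R/S estimation on windows of 256 samples carries a sampling spread of
  roughly ±0.1; trajectory-level statements are made about means, not
  single windows.
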