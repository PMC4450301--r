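#' Physical constants of the neural tissue
#'
#' The diffusion coefficient D of the tissue and the relaxation time tau
#' (the finite lag between stimulus and response; tau = D_eff / C^2 with C
#' the impulse propagation speed). The default D is the tissue diffusivity
#' used throughout the model (6.5e-4 m^2/s); tau has no canonical published
#' value, so the package default of 0.001 s (the same order as the default
#' stimulus width) is a deliberate, documented choice that should be set
#' explicitly for any serious use -- the command-line interface refuses to
#' run a prediction without it.
#'
#' @param D Diffusion coefficient in m^2/s, > 0.
#' @param tau Relaxation time in seconds, > 0.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(D = 6.5e-4, tau = 1e-3) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("'D' must be a single positive number")
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a single positive number")
  structure(list(D = D, tau = tau), class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("<tissue_params> D = %g m^2/s, tau = %g s\n", x$D, x$tau))
  invisible(x)
}

# Exponentially scaled zero-order modified Bessel function, I0(z) * exp(-z).
# base::besselI underflows to 0 for very large scaled arguments, so beyond
# z = 500 the standard large-argument asymptotic series is used; the two
# branches agree to ~1e-13 at the switch point.
bessel_i0_scaled <- function(z) {
  out <- numeric(length(z))
  small <- z < 500
  if (any(small)) out[small] <- besselI(z[small], 0, expon.scaled = TRUE)
  if (any(!small)) {
    zz <- z[!small]
    out[!small] <- (1 + 1 / (8 * zz) + 9 / (128 * zz^2) +
                      225 / (3072 * zz^3) + 11025 / (98304 * zz^4)) /
      sqrt(2 * pi * zz)
  }
  out
}

#' Dimensionless effective diffusivity D_eff / D
#'
#' The ratio of the time-dependent effective diffusivity of neural tissue
#' to its constant diffusivity, as a function of the dimensionless time
#' z = t / (2 tau) and the Hurst exponent H:
#'
#'   D_eff / D = \[2^(1-H) Gamma(H) z^(1-H) I0(z) exp(-z)\]^2,
#'
#' where I0 is the zero-order modified Bessel function, evaluated in
#' exponentially scaled form so large z does not overflow. The squared
#' bracket is required for consistency with the law's own limits: the
#' large-z asymptote 2^(1-2H) Gamma(H)^2 / pi * z^(1-2H), hence the limit
#' 1 at H = 0.5 and 0 for 0.5 < H <= 1. An unsquared variant is available
#' for comparison via `squared = FALSE` but does not satisfy those limits.
#'
#' The curve rises from 0 at z = 0 to a single interior maximum and then
#' decays toward its limit (1 for H = 0.5, 0 for H > 0.5); for H = 1 the
#' z-power vanishes and the curve decays monotonically from 1.
#'
#' @param z Dimensionless time, >= 0 (vectorised).
#' @param H Hurst exponent in (0, 1]; H = 0 is outside the domain (Gamma
#'   pole). Callers working with antipersistent H < 0.5 should reflect via
#'   [reflect_h()] first (or use [effective_diffusivity()], which does).
#' @param squared Use the limit-consistent squared form (default `TRUE`).
#' @return Dimensionless ratio(s) >= 0.
#' @examples
#' dimensionless_diffusivity(1e6, 0.5)  # ~1
#' dimensionless_diffusivity(1e8, 0.7)  # ~0
#' @export
dimensionless_diffusivity <- function(z, H, squared = TRUE) {
  if (!is.numeric(H) || length(H) != 1L || !is.finite(H) || H <= 0 || H > 1)
    stop("H must lie in (0, 1]")
  if (any(!is.finite(z)) || any(z < 0)) stop("z must be finite and >= 0")
  bracket <- 2^(1 - H) * gamma(H) * z^(1 - H) * bessel_i0_scaled(z)
  if (squared) bracket^2 else bracket
}

#' Large-z asymptote of the dimensionless diffusivity
#'
#' The power-law form 2^(1-2H) Gamma(H)^2 / pi * z^(1-2H) that the full
#' Bessel expression approaches as z grows; it equals 1 identically at
#' H = 0.5 and decays like z^(1-2H) for H > 0.5.
#'
#' @param z Dimensionless time, > 0 (vectorised).
#' @param H Hurst exponent in (0, 1].
#' @return Dimensionless ratio(s).
#' @export
asymptotic_ratio <- function(z, H) {
  if (!is.numeric(H) || length(H) != 1L || !is.finite(H) || H <= 0 || H > 1)
    stop("H must lie in (0, 1]")
  if (any(!is.finite(z)) || any(z <= 0)) stop("z must be finite and > 0")
  2^(1 - 2 * H) * gamma(H)^2 / pi * z^(1 - 2 * H)
}

#' Effective diffusivity at a given time
#'
#' D_eff(t) = D * (D_eff/D)(z = t / (2 tau), H). By default H is reflected
#' into the reference span [0.5, 1] before evaluation.
#'
#' @param t Time since stimulus application in seconds, >= 0 (vectorised).
#' @param H Hurst exponent in [0, 1] (reflected when `reflect = TRUE`).
#' @param params A [tissue_params()] object.
#' @param reflect Reflect H below 0.5 via [reflect_h()] (default `TRUE`).
#' @return Effective diffusivity in m^2/s.
#' @export
effective_diffusivity <- function(t, H, params, reflect = TRUE) {
  stopifnot(inherits(params, "tissue_params"))
  if (reflect) H <- reflect_h(H)
  params$D * dimensionless_diffusivity(t / (2 * params$tau), H)
}

#' Impulse propagation speed
#'
#' C = sqrt(D_eff / tau), the finite speed at which the disturbance
#' propagates; the inverse relation tau = D_eff / C^2 holds to round-off.
#'
#' @param D_eff Effective diffusivity in m^2/s, >= 0 (vectorised).
#' @param tau Relaxation time in seconds, > 0.
#' @return Speed in m/s.
#' @export
propagation_speed <- function(D_eff, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a single positive number")
  if (any(D_eff < 0)) stop("'D_eff' must be >= 0")
  sqrt(D_eff / tau)
}

#' Tabulated diffusivity curve
#'
#' Evaluates [dimensionless_diffusivity()] on a grid of z values, for
#' plotting or CSV export.
#'
#' @param H Hurst exponent in (0, 1].
#' @param z Grid of dimensionless times (default 500 points on (0, 50]).
#' @param squared Passed to [dimensionless_diffusivity()].
#' @return A data frame with columns `z` and `ratio`, with attribute `H`.
#' @export
diffusivity_curve <- function(H, z = seq(0.1, 50, length.out = 500),
                              squared = TRUE) {
  out <- data.frame(z = z, ratio = dimensionless_diffusivity(z, H, squared))
  attr(out, "H") <- H
  out
}
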