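# Periodised orthogonal discrete wavelet transform used by
# wavelet_denoise(). Implemented directly (pyramid algorithm with
# periodic boundary handling); correctness is pinned by the perfect-
# reconstruction property tests.

# Orthonormal scaling filters (sum = sqrt(2), unit energy). "db4" is the
# 8-tap Daubechies filter with four vanishing moments.
wavelet_filter <- function(name = c("db4", "haar")) {
  name <- match.arg(name)
  switch(name,
    haar = c(1, 1) / sqrt(2),
    db4 = c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983849,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278))
}

# Quadrature-mirror highpass from the lowpass filter.
qmf <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1L)
}

dwt_step <- function(a, h, g) {
  N <- length(a)
  L <- length(h)
  half <- N %/% 2L
  idx <- outer(2L * (seq_len(half) - 1L), seq_len(L) - 1L, `+`) %% N + 1L
  vals <- matrix(a[idx], nrow = half)
  list(a = drop(vals %*% h), d = drop(vals %*% g))
}

idwt_step <- function(a_next, d, h, g) {
  half <- length(a_next)
  N <- 2L * half
  L <- length(h)
  a <- numeric(N)
  for (k in seq_len(half)) {
    pos <- (2L * (k - 1L) + seq_len(L) - 1L) %% N + 1L
    a[pos] <- a[pos] + h * a_next[k] + g * d[k]
  }
  a
}

# Multi-level periodised DWT: returns list(approx, details = list(d1 =
# finest, ...)). Length of x must be divisible by 2^levels.
dwt_periodic <- function(x, wavelet = "db4", levels = 4L) {
  h <- wavelet_filter(wavelet)
  g <- qmf(h)
  if (length(x) %% 2L^levels != 0L)
    stop("length must be divisible by 2^levels")
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(a, h, g)
    details[[j]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, wavelet = wavelet, levels = levels)
}

idwt_periodic <- function(dec) {
  h <- wavelet_filter(dec$wavelet)
  g <- qmf(h)
  a <- dec$approx
  for (j in rev(seq_len(dec$levels))) a <- idwt_step(a, dec$details[[j]], h, g)
  a
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)
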