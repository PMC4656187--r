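# Small numerical helpers shared across modules.

#' Wrap angles into [0, 2*pi)
#'
#' @param x angles in radians.
#' @return angles wrapped into `[0, 2*pi)`.
#' @export
wrap_2pi <- function(x) x %% (2 * pi)

#' Smallest signed angular difference a - b, in (-pi, pi]
#' @param a,b angles in radians.
#' @return signed difference in `(-pi, pi]`.
#' @export
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Analytic signal via the discrete Hilbert transform
#'
#' Computes the analytic signal z(t) = x(t) + i*H[x](t) by one-sided spectral
#' weighting of the FFT. The instantaneous phase of a band-limited
#' oscillation is `Arg(z)` and its instantaneous amplitude `Mod(z)`.
#'
#' @param x real numeric vector, NA-free.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  if (anyNA(x)) stop("analytic_signal: input contains NA")
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Narrowband analytic signal by Fourier-domain masking
#'
#' One-step zero-phase band isolation: the FFT is masked to positive
#' frequencies within `freq +/- bandwidth/2` (doubled to preserve amplitude)
#' and inverted, yielding the analytic signal of the band-limited component.
#'
#' @param x real numeric vector, NA-free.
#' @param dt sampling interval, seconds.
#' @param freq band centre frequency, Hz.
#' @param bandwidth full bandwidth, Hz (default `freq/3`).
#' @return complex vector of the same length.
#' @export
band_analytic <- function(x, dt, freq, bandwidth = freq / 3) {
  if (anyNA(x)) stop("band_analytic: input contains NA")
  n <- length(x)
  fk <- (seq_len(n) - 1) / (n * dt)              # DFT bin frequencies
  keep <- fk >= (freq - bandwidth / 2) & fk <= (freq + bandwidth / 2) &
    fk <= 1 / (2 * dt)
  X <- stats::fft(x)
  X[!keep] <- 0i
  2 * stats::fft(X, inverse = TRUE) / n
}

#' Least-squares fit of a sinusoid at a known frequency
#'
#' Fits x(t) ~ A*cos(omega*t + phi) by linear regression on cos/sin
#' regressors; exact for noiseless data of any length not degenerate with
#' the period.
#'
#' @param x numeric vector of samples.
#' @param t sample times, seconds.
#' @param omega angular frequency, rad/s.
#' @return list with `amplitude`, `phase` (radians, in (-pi, pi]).
#' @export
sinusoid_fit <- function(x, t, omega) {
  C <- cos(omega * t); S <- sin(omega * t)
  fit <- stats::lm.fit(cbind(C, S), x)
  a <- fit$coefficients[[1]]; b <- fit$coefficients[[2]]
  list(amplitude = sqrt(a^2 + b^2), phase = atan2(-b, a))
}

# Centred moving average; NA at edges where the window is incomplete.
boxcar <- function(x, k) {
  if (k < 1) stop("boxcar: window must cover at least one sample")
  if (k == 1) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}

# Indices of strict local minima/maxima; plateaus contribute their midpoint.
local_extrema <- function(x, what = c("min", "max")) {
  what <- match.arg(what)
  if (what == "max") x <- -x
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # carry the sign of the last non-zero step through plateaus
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  sf <- s
  last <- 0
  for (i in seq_len(n - 1)) {
    if (sf[i] == 0) sf[i] <- last else last <- sf[i]
  }
  idx <- which(sf[-1] > 0 & sf[-(n - 1)] < 0) + 1
  # plateau minima: map to the midpoint of the flat run
  out <- vapply(idx, function(i) {
    j <- i
    while (j > 1 && x[j - 1] == x[i]) j <- j - 1
    as.integer(floor((i + j) / 2))
  }, integer(1))
  unique(out)
}

# Uniform sampling step with a relative tolerance check; returns dt or NA.
uniform_step <- function(times, tol = 0.01) {
  if (length(times) < 2) return(NA_real_)
  d <- diff(times)
  dt <- stats::median(d)
  if (any(abs(d - dt) > tol * dt)) return(NA_real_)
  dt
}

# First finite-difference derivative on a uniform grid (central, one-sided ends).
fd_derivative <- function(x, dt) {
  n <- length(x)
  if (n < 2) stop("fd_derivative: need at least two samples")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}

# Shoelace signed area of a closed polygon given ordered vertices.
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}
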