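# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Truncated Gaussian kernel on a uniform grid
#'
#' Kernel taps at spacing `dt`, truncated at 4 standard deviations and
#' normalized to unit sum, so smoothing preserves the mean of the input.
#'
#' @keywords internal
#' @noRd
gauss_kernel <- function(sigma, dt) {
  if (sigma <= 0 || dt <= 0) stopf("sigma and dt must be positive")
  half <- max(1L, ceiling(4 * sigma / dt))
  tt <- seq(-half, half) * dt
  k <- exp(-0.5 * (tt / sigma)^2)
  k / sum(k)
}

# FFT convolution of x with kernel k, "same" alignment (k assumed odd length,
# centered). Plain convolution, no padding policy: callers pad.
#' @keywords internal
#' @noRd
fft_conv_same <- function(x, k) {
  n <- length(x)
  nk <- length(k)
  half <- (nk - 1L) %/% 2L
  m <- stats::nextn(n + nk - 1L, c(2L, 3L, 5L))
  xp <- c(x, rep(0, m - n))
  kp <- c(k, rep(0, m - nk))
  full <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) / m
  full[(half + 1L):(half + n)]
}

#' Gaussian smoothing with reflection padding
#'
#' Smooths a uniformly sampled series with a Gaussian of standard deviation
#' `sigma` (seconds). Edges are handled by reflecting the series over 4 sigma
#' on both sides, so there is no amplitude loss at the boundaries.
#'
#' @param x numeric vector sampled at spacing `dt`.
#' @param sigma kernel standard deviation in seconds.
#' @param dt sample spacing in seconds.
#' @return smoothed numeric vector, same length as `x`.
#' @export
gaussian_smooth <- function(x, sigma, dt) {
  if (sigma < dt) stopf("sigma (%g s) must be at least one sample (%g s)", sigma, dt)
  n <- length(x)
  k <- gauss_kernel(sigma, dt)
  half <- (length(k) - 1L) %/% 2L
  pad <- min(half, n - 1L)
  xp <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  y <- fft_conv_same(xp, k)
  y[(pad + 1L):(pad + n)]
}

# Sum over valid t of x(t) * y(t + lag), for integer lags -max_lag..max_lag.
# Zero padding outside the series, computed in one FFT pass.
#' @keywords internal
#' @noRd
xcorr_sums <- function(x, y, max_lag) {
  n <- length(x)
  stopifnot(length(y) == n)
  # m >= n + max_lag guarantees no circular aliasing for lags -max_lag..max_lag
  m <- stats::nextn(n + max_lag + 1L, c(2L, 3L, 5L))
  fx <- stats::fft(c(x, rep(0, m - n)))
  fy <- stats::fft(c(y, rep(0, m - n)))
  cc <- Re(stats::fft(Conj(fx) * fy, inverse = TRUE)) / m
  # lag k >= 0 at index k + 1; lag k < 0 wraps to index m + k + 1
  idx <- ifelse(seq(-max_lag, max_lag) >= 0, seq(-max_lag, max_lag) + 1L,
                m + seq(-max_lag, max_lag) + 1L)
  out <- cc[idx]
  names(out) <- NULL
  out
}

# Shift a series by an integer number of bins: positive k moves content later
# in time (y[t] = x[t - k]); edges filled by replicating the boundary value.
#' @keywords internal
#' @noRd
shift_series <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(x)
  if (abs(k) >= n) return(rep(x[if (k > 0) 1L else n], n))
  if (k > 0) c(rep(x[1L], k), x[1L:(n - k)]) else c(x[(1L - k):n], rep(x[n], -k))
}

# Analytic signal via FFT (Hilbert transform); x must be real.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  h <- rep(0, n)
  if (n %% 2L == 0L) {
    h[c(1L, n %/% 2L + 1L)] <- 1
    h[2L:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) %/% 2L)] <- 2
  }
  stats::fft(f * h, inverse = TRUE) / n
}

#' @keywords internal
#' @noRd
pearson <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}

# Zero-phase Butterworth high-pass applied in the frequency domain: the
# squared magnitude response |H(f)|^2 = (f/fc)^(2p) / (1 + (f/fc)^(2p)) of a
# forward-backward p-th order Butterworth filter, multiplied onto the FFT of
# the (zero-padded) signal.
#' @keywords internal
#' @noRd
butter_highpass_zerophase <- function(x, fs, fc, order = 3L) {
  n <- length(x)
  m <- stats::nextn(n, c(2L, 3L, 5L))
  f <- c(seq(0, floor(m / 2)), -seq(ceiling(m / 2) - 1, 1)) * fs / m
  u <- (abs(f) / fc)^(2L * order)
  g <- u / (1 + u)
  y <- Re(stats::fft(stats::fft(c(x, rep(0, m - n))) * g, inverse = TRUE)) / m
  y[seq_len(n)]
}
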