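# Unit-specific decoding kernels and their frequency-domain analyses:
# generalized Morse continuous wavelet transform, rectified-derivative peak
# times, half-maximum rise latencies, and the segment bootstrap of kernel
# weights.

#' Continuous wavelet transform with generalized Morse wavelets
#'
#' Analytic CWT computed in the frequency domain with a generalized Morse
#' wavelet of symmetry (gamma) 1.5 and time-bandwidth product 2, evaluated on
#' a logarithmic frequency grid.
#'
#' @param x real signal on a uniform grid.
#' @param dt sample spacing in seconds.
#' @param freqs analysis frequencies in Hz; default 12 voices per octave
#'   between 0.25 and 30 Hz.
#' @param gamma Morse symmetry parameter (default 1.5).
#' @param time_bandwidth Morse time-bandwidth product (default 2), giving
#'   `beta = time_bandwidth / gamma`.
#' @return list with `freqs` and `amplitude` (matrix `length(freqs) x
#'   length(x)` of coefficient magnitudes).
#' @export
morse_cwt <- function(x, dt, freqs = NULL, gamma = 1.5, time_bandwidth = 2) {
  n <- length(x)
  if (is.null(freqs)) {
    n_oct <- log2(30 / 0.25)
    freqs <- 0.25 * 2^(seq(0, n_oct, by = 1 / 12))
  }
  beta <- time_bandwidth / gamma
  omega_peak <- (beta / gamma)^(1 / gamma)
  # angular frequencies of the FFT grid
  w <- 2 * pi * c(seq(0, floor(n / 2)), -seq(ceiling(n / 2) - 1, 1)) / (n * dt)
  fx <- stats::fft(x)
  amp <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    s <- omega_peak / (2 * pi * freqs[i])
    sw <- s * w
    psi <- numeric(n)
    pos <- sw > 0
    psi[pos] <- 2 * exp(beta * log(sw[pos]) - sw[pos]^gamma -
                          (beta * log(omega_peak) - omega_peak^gamma))
    coef <- stats::fft(fx * psi, inverse = TRUE) / n
    amp[i, ] <- Mod(coef)
  }
  list(freqs = freqs, amplitude = amp)
}

# Latency at which a kernel reaches half of its extremum (max, or min for a
# negative deflection), linearly interpolated on the rising flank before the
# extremum. NA when the kernel is all zero.
#' @keywords internal
#' @noRd
half_max_latency <- function(kern, lags_s) {
  if (all(kern == 0)) return(NA_real_)
  ipk <- which.max(abs(kern))
  sgn <- sign(kern[ipk])
  k <- sgn * kern # extremum now a positive maximum
  half <- 0.5 * k[ipk]
  j <- ipk
  while (j > 1L && k[j - 1L] >= half) j <- j - 1L
  if (j == 1L) return(lags_s[1L])
  frac <- (k[j] - half) / (k[j] - k[j - 1L])
  lags_s[j] - frac * (lags_s[j] - lags_s[j - 1L])
}

#' Unit-specific decoding kernels and their temporal-frequency structure
#'
#' Fits, for each unit and velocity axis independently, the T x 1 temporal
#' kernel (lags -2 to 2 s, 10 ms) that decodes the paw velocity from that
#' unit's activity by least squares. Kernels are reported as a function of
#' the activity's time relative to the behavior sample, so negative times
#' mean the unit's activity precedes the movement. From the kernels it derives: the
#' average generalized-Morse wavelet amplitude map, the time of the largest
#' rectified temporal derivative per kernel, the half-maximum (or minimum)
#' rise latency per kernel, and the SD of those latencies across units
#' (latency variability). Kernel-weight variability is estimated by
#' bootstrapping across 10 s segments via [kernel_weight_variability()].
#'
#' @param sess a [session()] with >= 5 units.
#' @param rate_sigma rate smoothing SD (s); default 0, i.e. kernels are fit
#'   on the raw binned rates. Smoothing the regressor removes the white
#'   noise floor of the spike counts and makes the whitening step of the
#'   least-squares kernel ill-conditioned at high frequencies.
#' @param lags kernel lags in bins (default `-200:199`).
#' @param axis which velocity axes to analyze (default both).
#' @return object of class `unit_kernel_analysis`: list with `kernels`
#'   (list over units of T x axes matrices), `lags_s`, `wavelet` (averaged
#'   amplitude map + freqs), `deriv_peak_time`, `half_max_latency` (per unit
#'   x axis matrices), `latency_sd`.
#' @export
unit_kernel_analysis <- function(sess, rate_sigma = 0, lags = -200:199,
                                 axis = 1:2) {
  stopifnot(inherits(sess, "session"))
  if (length(sess$units) < 5) stopf("need >= 5 units")
  beh <- sess$behavior
  dt <- beh$dt
  V <- cbind(beh$vx, beh$vy)[, axis, drop = FALSE]
  U <- length(sess$units)
  # report kernels on the behavior-relative time axis: a weight that reads
  # the activity l bins before the behavior sample sits at -l, so negative
  # times mean the activity precedes the movement
  ord <- order(-lags)
  lags_s <- sort(-lags) * dt
  kernels <- vector("list", U)
  dpt <- hml <- matrix(NA_real_, U, ncol(V))
  wav_acc <- NULL
  for (u in seq_len(U)) {
    a <- instantaneous_rate(sess$units[[u]], sess$duration, dt, rate_sigma)
    km <- matrix(0, length(lags), ncol(V))
    for (ax in seq_len(ncol(V))) {
      fit <- fit_lagged_kernel(a, V[, ax], lags)
      km[, ax] <- fit$weights[ord, 1L]
      kern <- km[, ax]
      if (any(kern != 0)) {
        d <- abs(diff(kern)) / dt
        dpt[u, ax] <- lags_s[which.max(d)] + dt / 2
        hml[u, ax] <- half_max_latency(kern, lags_s)
        cw <- morse_cwt(kern, dt)
        wav_acc <- if (is.null(wav_acc)) cw$amplitude else wav_acc + cw$amplitude
      }
    }
    kernels[[u]] <- km
  }
  n_k <- sum(!is.na(dpt))
  cw0 <- morse_cwt(numeric(length(lags)), dt)
  structure(list(kernels = kernels, lags_s = lags_s,
                 wavelet = list(freqs = cw0$freqs,
                                amplitude = if (is.null(wav_acc)) NULL else
                                  wav_acc / n_k,
                                lags_s = lags_s),
                 deriv_peak_time = dpt, half_max_latency = hml,
                 latency_sd = stats::sd(as.vector(hml), na.rm = TRUE)),
            class = "unit_kernel_analysis")
}

#' @export
print.unit_kernel_analysis <- function(x, ...) {
  cat(sprintf("<unit_kernel_analysis> %d units, latency SD %.3f s\n",
              length(x$kernels), x$latency_sd))
  invisible(x)
}

#' Segment bootstrap of decoding-kernel weights
#'
#' Splits the session into contiguous segments (10 s by default), computes
#' the normal-equation sums per segment, resamples segments with replacement
#' and re-solves the kernel per repetition. Returns the per-lag SD of the
#' kernel weights across repetitions.
#'
#' @param x regressor trace (a unit's activity).
#' @param y target trace (one velocity axis).
#' @param dt sample spacing (s).
#' @param segment_len segment length in seconds (default 10).
#' @param n_reps bootstrap repetitions (default 100).
#' @param lags kernel lags in bins.
#' @param seed integer seed.
#' @return list with `sd` (per-lag SD), `lags_s`, `mean` (per-lag mean).
#' @export
kernel_weight_variability <- function(x, y, dt = 0.01, segment_len = 10,
                                      n_reps = 100, lags = -200:199, seed = 1) {
  n <- length(x)
  stopifnot(length(y) == n)
  set.seed(as.integer(seed))
  seg_bins <- round(segment_len / dt)
  n_seg <- max(2L, n %/% seg_bins)
  bounds <- floor(seq(0, n, length.out = n_seg + 1L))
  xc <- x - mean(x); yc <- y - mean(y)
  T_ <- length(lags)
  dmat <- outer(lags, lags, `-`)
  seg_sums <- lapply(seq_len(n_seg), function(s) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    cc <- circ_ccf(xc[idx], xc[idx])
    cb <- circ_ccf(xc[idx], yc[idx])
    list(G = matrix(circ_at(cc, as.vector(dmat)), T_, T_),
         b = circ_at(cb, lags))
  })
  W <- matrix(0, T_, n_reps)
  for (r in seq_len(n_reps)) {
    pick <- sample.int(n_seg, n_seg, replace = TRUE)
    G <- Reduce(`+`, lapply(seg_sums[pick], `[[`, "G"))
    b <- Reduce(`+`, lapply(seg_sums[pick], `[[`, "b"))
    W[, r] <- tryCatch(solve(G, b), error = function(e)
      solve(G + diag(1e-8 * max(diag(G)), T_), b))
  }
  list(sd = apply(W, 1L, stats::sd), mean = rowMeans(W), lags_s = lags * dt)
}
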