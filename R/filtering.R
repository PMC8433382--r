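# Subtractive-Gaussian filtering: high-pass by subtracting a Gaussian-smoothed
# copy, band-pass by re-smoothing the high-passed signal, rectified envelopes,
# band-velocity correlation, and phase-amplitude cross-frequency coupling.
#
# The sigma <-> cutoff convention throughout is f_c = 1 / (2 * pi * sigma): at
# the cutoff a Gaussian low-pass passes a sinusoid with gain exp(-1/2).

#' Band specification for subtractive-Gaussian filtering
#'
#' A band is defined by two Gaussian smoothing stages: the high-pass stage
#' (subtract the sigma_highpass-smoothed signal) removes content below
#' 1/(2*pi*sigma_highpass) Hz, and the low-pass stage (smooth the result with
#' sigma_lowpass) removes content above 1/(2*pi*sigma_lowpass) Hz, which
#' labels the band.
#'
#' @param sigma_highpass Gaussian SD (s) of the subtracted smoothing stage.
#' @param sigma_lowpass Gaussian SD (s) of the final smoothing stage.
#' @return an object of class `band_spec` with fields `sigma_highpass`,
#'   `sigma_lowpass` and `center_freq` (Hz, the low-pass stage cutoff).
#' @seealso [default_bands()], [band_spec_from_center()]
#' @export
band_spec <- function(sigma_highpass, sigma_lowpass) {
  if (!(sigma_highpass > sigma_lowpass && sigma_lowpass > 0))
    stopf("need sigma_highpass > sigma_lowpass > 0")
  structure(list(sigma_highpass = sigma_highpass,
                 sigma_lowpass = sigma_lowpass,
                 center_freq = gaussian_cutoff(sigma_lowpass)),
            class = "band_spec")
}

#' Nominal cutoff frequency of a Gaussian smoothing kernel
#'
#' @param sigma Gaussian SD in seconds.
#' @return cutoff frequency in Hz, `1 / (2 * pi * sigma)`. A sinusoid at this
#'   frequency is passed with amplitude gain `exp(-1/2)` (about 0.607).
#' @export
gaussian_cutoff <- function(sigma) 1 / (2 * pi * sigma)

#' Construct a band from its center frequency
#'
#' Follows the fixed ratio of the default band table: the low-pass cutoff
#' equals the band label and the high-pass cutoff is a quarter of it, i.e.
#' `sigma_lowpass = 1/(2*pi*f)` and `sigma_highpass = 4/(2*pi*f)`.
#'
#' @param center_freq band label in Hz.
#' @export
band_spec_from_center <- function(center_freq) {
  band_spec(4 / (2 * pi * center_freq), 1 / (2 * pi * center_freq))
}

#' Default band-pass filter bank
#'
#' Seven bands whose high-pass stage SDs are 0.057, 0.14, 0.28, 0.57, 1.4,
#' 2.8 and 5.7 s and whose low-pass stage SDs are 0.014, 0.035, 0.071, 0.14,
#' 0.35, 0.71 and 1.4 s, giving nominal band labels of 11, 4.5, 2.2, 1.1,
#' 0.45, 0.22 and 0.11 Hz. The band built from the 0.71 s low-pass and 2.8 s
#' high-pass stages (0.22 Hz) is the named "low-pass" preset.
#'
#' @return named list of [band_spec()] objects, names are the labels in Hz.
#' @export
default_bands <- function() {
  hp <- c(0.057, 0.14, 0.28, 0.57, 1.4, 2.8, 5.7)
  lp <- c(0.014, 0.035, 0.071, 0.14, 0.35, 0.71, 1.4)
  bands <- Map(band_spec, hp, lp)
  names(bands) <- vapply(bands, function(b) format(round(b$center_freq, 2)), "")
  bands
}

#' The low-frequency preset band (0.22 Hz low-pass, 0.057 Hz high-pass)
#' @export
lowpass_band <- function() band_spec(2.8, 0.71)

#' Subtractive-Gaussian high-pass filter
#'
#' @param x uniformly sampled signal.
#' @param sigma SD (s) of the subtracted Gaussian smoothing.
#' @param dt sample spacing in seconds (default 0.01).
#' @return `x - gaussian_smooth(x, sigma)`.
#' @export
high_pass <- function(x, sigma, dt = 0.01) x - gaussian_smooth(x, sigma, dt)

#' Subtractive-Gaussian band-pass filter
#'
#' High-passes with the band's `sigma_highpass` stage, then smooths the result
#' with the `sigma_lowpass` stage.
#'
#' @param x uniformly sampled signal (10 ms grid by default).
#' @param band a [band_spec()].
#' @param dt sample spacing in seconds.
#' @export
band_pass <- function(x, band, dt = 0.01) {
  stopifnot(inherits(band, "band_spec"))
  if (band$sigma_lowpass < dt)
    stopf("band sigma_lowpass (%g s) shorter than one sample", band$sigma_lowpass)
  gaussian_smooth(high_pass(x, band$sigma_highpass, dt), band$sigma_lowpass, dt)
}

#' Rectified envelope of a filtered signal
#'
#' The energy of a band-passed signal is taken as its absolute value,
#' optionally smoothed with a further Gaussian stage.
#'
#' @param x band-pass-filtered signal.
#' @param smooth_sigma optional Gaussian SD (s) for smoothing the rectified
#'   signal; `NULL` (default) leaves it unsmoothed.
#' @param dt sample spacing in seconds.
#' @export
envelope <- function(x, smooth_sigma = NULL, dt = 0.01) {
  e <- abs(x)
  if (!is.null(smooth_sigma)) e <- gaussian_smooth(e, smooth_sigma, dt)
  e
}

#' Correlation between band-limited population activity and paw speed
#'
#' For each band, the per-unit activity traces are band-passed and rectified,
#' the envelopes are averaged across units, and the Pearson correlation with
#' paw speed is computed at every lag in `±max_lag`. Negative lags mean the
#' neural envelope leads the movement.
#'
#' @param activity matrix units x time bins (10 ms grid) of continuous
#'   activity (e.g. Gaussian-smoothed instantaneous rates), or a single trace.
#' @param behavior a [behavior_trace()].
#' @param bands list of [band_spec()]s, default [default_bands()].
#' @param max_lag maximum lag in seconds (default 4).
#' @return data.frame with one row per band: `center_freq`, `peak_r`,
#'   `peak_lag` (s), plus attribute `curves` holding the per-band lag curves.
#' @export
band_velocity_correlation <- function(activity, behavior, bands = default_bands(),
                                      max_lag = 4) {
  stopifnot(inherits(behavior, "behavior_trace"))
  if (is.null(dim(activity))) activity <- matrix(activity, nrow = 1)
  dt <- behavior$dt
  sp <- speed(behavior)
  n <- length(sp)
  stopifnot(ncol(activity) == n)
  L <- round(max_lag / dt)
  lags <- seq(-L, L) * dt
  curves <- lapply(bands, function(b) {
    envs <- vapply(seq_len(nrow(activity)),
                   function(i) envelope(band_pass(activity[i, ], b, dt)),
                   numeric(n))
    env <- rowMeans(envs)
    if (stats::sd(env) == 0) return(rep(NA_real_, 2L * L + 1L))
    # r(lag) = cor(env(t + lag), speed(t)); negative lag = envelope earlier
    se <- xcorr_sums(sp - mean(sp), env - mean(env), L)
    nn <- xcorr_sums(rep(1, n), rep(1, n), L) # overlap counts
    # normalize with overall SDs (long series; edge effects negligible)
    se / nn / (stats::sd(env) * stats::sd(sp))
  })
  res <- data.frame(
    center_freq = vapply(bands, function(b) b$center_freq, 0),
    peak_r = vapply(curves, function(cv) if (all(is.na(cv))) NA_real_ else max(cv, na.rm = TRUE), 0),
    peak_lag = vapply(curves, function(cv) if (all(is.na(cv))) NA_real_ else lags[which.max(cv)], 0),
    row.names = NULL
  )
  attr(res, "curves") <- curves
  attr(res, "lags") <- lags
  res
}

#' Phase-amplitude cross-frequency coupling profile
#'
#' Band-passes the signal around a slow and a fast center frequency, takes the
#' instantaneous phase of the slow band (Hilbert transform) and the amplitude
#' of the fast band (rectified, then smoothed with a 1.5 Hz Gaussian stage),
#' and averages the fast amplitude within 16 evenly divided slow-phase bins
#' spanning (-pi, pi].
#'
#' @param x activity trace on a uniform 10 ms grid.
#' @param slow_freq slow band center in Hz (default 0.1).
#' @param fast_freq fast band center in Hz (default 3).
#' @param dt sample spacing in seconds.
#' @param amp_smooth_freq cutoff (Hz) of the Gaussian smoothing applied to the
#'   rectified fast band (default 1.5).
#' @return object of class `cfc_profile`: data.frame with `phase` (bin
#'   centers) and `amplitude` (mean fast amplitude per bin).
#' @export
cross_frequency_coupling <- function(x, slow_freq = 0.1, fast_freq = 3,
                                     dt = 0.01, amp_smooth_freq = 1.5) {
  n_cycles <- length(x) * dt * slow_freq
  if (n_cycles < 10)
    stopf("signal covers %.1f slow cycles; need >= 10", n_cycles)
  slow <- band_pass(x, band_spec_from_center(slow_freq), dt)
  fast <- band_pass(x, band_spec_from_center(fast_freq), dt)
  amp <- envelope(fast, smooth_sigma = 1 / (2 * pi * amp_smooth_freq), dt = dt)
  phase <- Arg(analytic_signal(slow))
  edges <- seq(-pi, pi, length.out = 17L)
  bin <- cut(phase, edges, include.lowest = TRUE, labels = FALSE)
  profile <- vapply(seq_len(16L), function(b) {
    if (!any(bin == b)) return(NA_real_)
    mean(amp[bin == b])
  }, 0)
  structure(data.frame(phase = (edges[-17L] + edges[-1L]) / 2,
                       amplitude = profile),
            class = c("cfc_profile", "data.frame"))
}
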