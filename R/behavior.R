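# Synthetic 2-D paw-velocity traces: quasi-periodic sub-movements gated by an
# alternation between quiescent and active epochs, plus white tracking noise.

#' Behavior trace container
#'
#' Uniformly sampled 2-D paw velocity. Optionally carries integrated paw
#' position and the tracking-noise SD used to generate (or estimated for)
#' the trace.
#'
#' @param vx,vy velocity components in cm/s per bin (equal length, finite).
#' @param dt sample spacing in seconds (default 0.01).
#' @param t0 time of the first sample in seconds.
#' @param x,y optional position in cm per bin.
#' @param tracking_noise_sd per-axis tracking noise SD in cm/s.
#' @return object of class `behavior_trace`.
#' @export
behavior_trace <- function(vx, vy, dt = 0.01, t0 = 0, x = NULL, y = NULL,
                           tracking_noise_sd = 0) {
  if (length(vx) != length(vy)) stopf("vx and vy must have the same length")
  if (dt <= 0) stopf("dt must be positive")
  if (!all(is.finite(vx)) || !all(is.finite(vy))) stopf("velocities must be finite")
  structure(list(vx = vx, vy = vy, dt = dt, t0 = t0, x = x, y = y,
                 tracking_noise_sd = tracking_noise_sd),
            class = "behavior_trace")
}

#' @export
print.behavior_trace <- function(x, ...) {
  cat(sprintf("<behavior_trace> %d bins, dt = %g s (%.1f s), mean speed %.2f cm/s\n",
              length(x$vx), x$dt, length(x$vx) * x$dt, mean(speed(x))))
  invisible(x)
}

#' Paw speed (Euclidean norm of the velocity components)
#' @param behavior a [behavior_trace()].
#' @export
speed <- function(behavior) {
  stopifnot(inherits(behavior, "behavior_trace"))
  sqrt(behavior$vx^2 + behavior$vy^2)
}

#' @export
length.behavior_trace <- function(x) length(x$vx)

#' Times of the behavior samples in seconds
#' @param behavior a [behavior_trace()].
#' @export
behavior_times <- function(behavior) {
  behavior$t0 + (seq_along(behavior$vx) - 1L) * behavior$dt
}

#' Generate a minimally repetitive sub-movement behavior trace
#'
#' Movement is modeled as quasi-periodic sub-movements: the speed oscillates
#' around an amplitude set-point at the sub-movement frequency (narrow-band
#' Gaussian noise, so successive sub-movements are decorrelated), gated by a
#' two-state semi-Markov alternation between quiescent and active epochs with
#' exponentially distributed dwell times. The movement direction performs a
#' slow random walk, and independent white tracking noise is added to each
#' velocity component.
#'
#' @param duration session length in seconds (>= 60).
#' @param dt sample spacing in seconds (default 0.01).
#' @param submovement_freq sub-movement rate in Hz (default 4.7, the typical
#'   peak of a locomotor speed spectrum; 4.3 for a joystick-like session).
#' @param submovement_bw relative bandwidth of the sub-movement oscillation
#'   (SD of its spectral peak as a fraction of `submovement_freq`); wider
#'   bands decorrelate the behavior faster. Default 0.25.
#' @param amplitude typical active-epoch speed in cm/s (default 6). Zero
#'   yields pure tracking noise.
#' @param depth modulation depth of the speed oscillation around the
#'   amplitude set-point, in (0, 1]; default 0.9.
#' @param dwell_active,dwell_quiescent mean dwell times (s) of the active and
#'   quiescent states (defaults 3 and 1).
#' @param direction_tau time constant (s) of the heading random walk
#'   (default 0.5).
#' @param tracking_noise_sd per-axis white tracking noise SD in cm/s
#'   (default 0.79).
#' @param seed integer seed; all randomness derives from it.
#' @return a [behavior_trace()]; the noise-free speed is stored in attribute
#'   `true_speed` for ground-truth comparisons.
#' @export
generate_behavior <- function(duration, dt = 0.01, submovement_freq = 4.7,
                              submovement_bw = 0.25, amplitude = 6,
                              depth = 0.9, dwell_active = 3,
                              dwell_quiescent = 1, direction_tau = 0.5,
                              tracking_noise_sd = 0.79, seed = 1) {
  if (duration < 60) stopf("duration must be >= 60 s")
  if (dt <= 0) stopf("dt must be positive")
  set.seed(as.integer(seed))
  n <- round(duration / dt)

  # narrow-band unit-variance oscillation at the sub-movement frequency:
  # white noise shaped by a Gaussian spectral window centered at +-f0
  f <- c(seq(0, floor(n / 2)), -seq(ceiling(n / 2) - 1, 1)) / (n * dt)
  w <- stats::rnorm(n)
  bw <- submovement_bw * submovement_freq
  shape <- exp(-0.5 * ((abs(f) - submovement_freq) / bw)^2)
  z <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  z <- z / stats::sd(z)

  # two-state semi-Markov gate on sub-movement amplitude
  gate <- numeric(n)
  t_idx <- 1L
  state <- 1L # start active
  while (t_idx <= n) {
    dwell <- stats::rexp(1, 1 / if (state == 1L) dwell_active else dwell_quiescent)
    len <- max(1L, round(dwell / dt))
    gate[t_idx:min(n, t_idx + len - 1L)] <- state
    t_idx <- t_idx + len
    state <- 1L - state
  }
  gate <- gaussian_smooth(gate, 0.15, dt) # soft epoch edges

  sp <- pmax(0, gate * amplitude * (1 + depth * z))

  # slow heading random walk
  theta <- cumsum(stats::rnorm(n, sd = sqrt(dt / direction_tau)))
  vx <- sp * cos(theta) + stats::rnorm(n, sd = tracking_noise_sd)
  vy <- sp * sin(theta) + stats::rnorm(n, sd = tracking_noise_sd)

  bt <- behavior_trace(vx, vy, dt = dt,
                       tracking_noise_sd = tracking_noise_sd)
  attr(bt, "true_speed") <- sp
  bt
}

#' Estimate the sub-movement frequency of a behavior trace
#'
#' The sub-movement rhythm is the quasi-periodic alternation of velocity
#' peaks and troughs. Epoch gating (quiescence vs movement) adds power at
#' very low frequencies that does not reflect sub-movement timing, so the
#' speed is first high-passed at 1 Hz with the subtractive-Gaussian filter
#' and the peak of the smoothed periodogram is returned.
#'
#' @param behavior a [behavior_trace()].
#' @param highpass_freq cutoff (Hz) of the gating-removal high-pass
#'   (default 1).
#' @return estimated sub-movement frequency in Hz.
#' @export
submovement_frequency <- function(behavior, highpass_freq = 1) {
  sp <- speed(behavior)
  dt <- behavior$dt
  hp <- high_pass(sp, 1 / (2 * pi * highpass_freq), dt)
  pg <- stats::spec.pgram(stats::ts(hp, deltat = dt), spans = c(11, 11),
                          taper = 0.1, plot = FALSE, detrend = TRUE)
  pg$freq[which.max(pg$spec)]
}
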