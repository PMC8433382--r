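# Ground-truth sessions: velocity-modulated inhomogeneous Poisson units on
# top of a synthetic behavior trace.

#' Specification of a velocity-modulated unit
#'
#' The unit's instantaneous rate is
#' `baseline_rate + gain * g(smooth(speed shifted by -lag))`, floored at 0,
#' where the Gaussian smoothing SD `modulation_sigma` controls the duration
#' of the velocity modulation and `lag` its timing: negative lags mean the
#' unit's activity precedes the movement (planning-like), positive lags that
#' it follows the movement (sensory-like).
#'
#' @param lag temporal lag in seconds (negative = unit leads movement).
#' @param modulation_sigma Gaussian SD (s) of the rate smoothing (> 0).
#' @param gain rate gain in Hz per (cm/s); may be 0 for unmodulated units.
#' @param baseline_rate baseline firing rate in Hz (>= 0).
#' @param area cortical area label: "S1", "M1" or "M2".
#' @param nonlinearity link between the behavioral drive and the rate:
#'   "linear" (identity) or "exponential" (`exp(drive / d0) - 1` with `d0`
#'   the mean drive, so tuning accelerates with the drive).
#' @param variable behavioral variable driving the unit: "speed" (default),
#'   or a signed velocity component "vx" / "vy".
#' @return object of class `unit_spec`.
#' @export
unit_spec <- function(lag = -0.1, modulation_sigma = 0.1, gain = 1,
                      baseline_rate = 5, area = c("M1", "S1", "M2"),
                      nonlinearity = c("linear", "exponential"),
                      variable = c("speed", "vx", "vy")) {
  if (baseline_rate < 0) stopf("baseline_rate must be >= 0")
  if (modulation_sigma <= 0) stopf("modulation_sigma must be > 0")
  structure(list(lag = lag, modulation_sigma = modulation_sigma, gain = gain,
                 baseline_rate = baseline_rate,
                 area = match.arg(area),
                 nonlinearity = match.arg(nonlinearity),
                 variable = match.arg(variable)),
            class = "unit_spec")
}

#' Recording session container
#'
#' @param behavior a [behavior_trace()].
#' @param units list of [sorted_unit()]s (>= 1).
#' @param task task label, "locomotor" or "joystick".
#' @param seed seed the session was generated with (NA for real data).
#' @return object of class `session`.
#' @export
session <- function(behavior, units, task = c("locomotor", "joystick"),
                    seed = NA_integer_) {
  stopifnot(inherits(behavior, "behavior_trace"))
  if (length(units) < 1) stopf("a session needs at least one unit")
  duration <- length(behavior) * behavior$dt
  for (u in units) {
    stopifnot(inherits(u, "sorted_unit"))
    if (length(u$spike_times) &&
        (min(u$spike_times) < 0 || max(u$spike_times) > duration))
      stopf("spike times outside [0, %g]", duration)
  }
  structure(list(behavior = behavior, units = units,
                 task = match.arg(task), duration = duration,
                 seed = seed),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> %s, %.0f s, %d units (%s)\n", x$task, x$duration,
              length(x$units),
              paste(table(vapply(x$units, `[[`, "", "area")), collapse = "/")))
  invisible(x)
}

# Ground-truth rate of one unit given the behavioral drive trace.
#' @keywords internal
#' @noRd
unit_rate <- function(spec, sp, dt) {
  drive <- switch(spec$nonlinearity,
                  linear = sp,
                  exponential = expm1(sp / max(mean(abs(sp)), .Machine$double.eps)))
  # negative lag = unit leads movement = rate reflects *future* speed:
  # drive(t) = speed(t - lag/dt), so lag = -0.2 s reads speed 0.2 s ahead
  shifted <- shift_series(drive, round(spec$lag / dt))
  pmax(0, spec$baseline_rate + spec$gain * gaussian_smooth(shifted, spec$modulation_sigma, dt))
}

#' Generate a session of velocity-modulated Poisson units
#'
#' Each unit's instantaneous rate is built from its behavioral drive -- the
#' noise-free speed (if the trace was generated here; measured speed
#' otherwise) or a signed velocity component, per the spec's `variable` --
#' shifted by the unit's lag, smoothed with its modulation SD, passed
#' through its nonlinearity and floored at zero; spikes are drawn from an
#' inhomogeneous Poisson process by thinning. Ground-truth rate, lag and modulation SD are
#' stored per unit.
#'
#' @param behavior a [behavior_trace()].
#' @param unit_specs non-empty list of [unit_spec()]s.
#' @param task task label for the session.
#' @param seed integer seed.
#' @param max_rate rates above this value (Hz) are treated as a
#'   configuration error (default 500).
#' @return a [session()]; each unit carries attributes `true_rate`,
#'   `true_lag` and `true_sigma`.
#' @export
generate_session <- function(behavior, unit_specs, task = "locomotor",
                             seed = 1, max_rate = 500) {
  stopifnot(inherits(behavior, "behavior_trace"))
  if (length(unit_specs) < 1) stopf("unit_specs must be non-empty")
  set.seed(as.integer(seed))
  dt <- behavior$dt
  sp <- attr(behavior, "true_speed")
  if (is.null(sp)) sp <- speed(behavior)
  duration <- length(behavior) * dt
  units <- lapply(seq_along(unit_specs), function(i) {
    spec <- unit_specs[[i]]
    drive <- switch(spec$variable, speed = sp, vx = behavior$vx,
                    vy = behavior$vy)
    rate <- unit_rate(spec, drive, dt)
    if (max(rate) > max_rate)
      stopf("unit %d: rate %.1f Hz exceeds max_rate %g", i, max(rate), max_rate)
    # thinning: homogeneous candidates at the rate ceiling
    rmax <- max(rate, .Machine$double.eps)
    n_cand <- stats::rpois(1, rmax * duration)
    cand <- sort(stats::runif(n_cand, 0, duration))
    keep <- stats::runif(n_cand) < rate[pmin(length(rate), floor(cand / dt) + 1L)] / rmax
    st <- cand[keep]
    u <- sorted_unit(st, area = spec$area, duration = duration)
    attr(u, "true_rate") <- rate
    attr(u, "true_lag") <- spec$lag
    attr(u, "true_sigma") <- spec$modulation_sigma
    u
  })
  session(behavior, units, task = task, seed = as.integer(seed))
}

#' Generate a population activity matrix with AR(1) temporal structure
#'
#' Each unit's activity is an independent first-order autoregressive process
#' on the 10 ms grid with autocorrelation `exp(-delta/tau)`, used as ground
#' truth for the population-correlation time-constant analysis. `tau` may be
#' a vector over time bins to emulate epochs with different dynamics.
#'
#' @param n_units number of units.
#' @param n_bins number of 10 ms time bins.
#' @param tau correlation time constant(s) in seconds (scalar or length
#'   `n_bins`).
#' @param dt bin width in seconds.
#' @param seed integer seed.
#' @return matrix `n_units x n_bins`.
#' @export
generate_population_ar1 <- function(n_units, n_bins, tau, dt = 0.01, seed = 1) {
  set.seed(as.integer(seed))
  phi <- exp(-dt / rep_len(tau, n_bins))
  out <- matrix(0, n_units, n_bins)
  innov_sd <- sqrt(1 - phi^2)
  for (u in seq_len(n_units)) {
    e <- stats::rnorm(n_bins)
    x <- numeric(n_bins)
    x[1] <- e[1]
    for (t in 2:n_bins) x[t] <- phi[t] * x[t - 1] + innov_sd[t] * e[t]
    out[u, ] <- x
  }
  out
}

#' Generate a session with fast execution coding and slow planning coding
#'
#' Builds an anterior-posterior velocity trace as the sum of a slow
#' Ornstein-Uhlenbeck component and a fast narrow-band component, then
#' drives two unit populations from it: execution units (short lag, small
#' modulation SD, dominated by the fast component) and planning units (long
#' negative lag, large modulation SD, retaining only the slow component).
#' Used as ground truth for the output-potent/output-null analysis: the
#' reduced lag-tuning trajectory wiggles fast along the execution direction
#' and drifts slowly along the planning direction.
#'
#' @param seed integer seed.
#' @param duration session length in seconds (default 300).
#' @param dt sample spacing in seconds.
#' @param n_exec,n_plan units per population (default 8 each).
#' @param exec_lag,plan_lag population lags in seconds (defaults -0.04 and
#'   -0.6).
#' @param fast_freq center frequency (Hz) of the fast velocity component
#'   (default 3).
#' @param slow_tau OU time constant (s) of the slow component (default 0.5).
#' @param slow_sd,fast_sd component SDs in cm/s (defaults 2 and 4).
#' @param gain_exec,gain_plan rate gains in Hz/(cm/s).
#' @param baseline_rate baseline rate in Hz.
#' @return a [session()].
#' @export
generate_planning_execution_session <- function(seed, duration = 300,
                                                dt = 0.01, n_exec = 8,
                                                n_plan = 8, exec_lag = -0.04,
                                                plan_lag = -0.6,
                                                fast_freq = 3, slow_tau = 0.5,
                                                slow_sd = 2, fast_sd = 4,
                                                gain_exec = 2, gain_plan = 4,
                                                baseline_rate = 10) {
  set.seed(as.integer(seed))
  n <- round(duration / dt)
  phi <- exp(-dt / slow_tau)
  slow <- as.numeric(stats::filter(stats::rnorm(n, sd = sqrt(1 - phi^2)),
                                   phi, "recursive"))
  f <- c(seq(0, floor(n / 2)), -seq(ceiling(n / 2) - 1, 1)) / (n * dt)
  shape <- exp(-0.5 * ((abs(f) - fast_freq) / (fast_freq / 3))^2)
  fast <- Re(stats::fft(stats::fft(stats::rnorm(n)) * shape, inverse = TRUE)) / n
  fast <- fast / stats::sd(fast)
  vx <- slow_sd * slow + fast_sd * fast
  beh <- behavior_trace(vx, stats::rnorm(n, sd = 0.79),
                        tracking_noise_sd = 0.79)
  specs <- c(
    lapply(seq_len(n_exec), function(i)
      unit_spec(lag = exec_lag, modulation_sigma = 0.02, gain = gain_exec,
                baseline_rate = baseline_rate, area = "M1",
                variable = "vx")),
    lapply(seq_len(n_plan), function(i)
      unit_spec(lag = plan_lag, modulation_sigma = 0.3, gain = gain_plan,
                baseline_rate = baseline_rate, area = "M2",
                variable = "vx")))
  generate_session(beh, specs, seed = as.integer(seed) + 1L)
}
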