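# Population-vector normalization, global-mode removal, velocity-based trial
# detection, within-trial correlation matrices, and exponential decay time
# constants of the population correlation.

#' Normalized population activity matrix
#'
#' Builds the units x time-bins activity matrix (Gaussian-smoothed
#' instantaneous rates on the 10 ms grid), z-scores each unit, demeans and
#' unit-norms every column, and removes a global population mode `p` by
#' subtracting each column's projection onto it
#' (`a_t - p (a_t . p)`). Silent units (zero SD) are excluded.
#'
#' The global mode captures arousal-like state changes (e.g. freezing) that
#' are shared across the whole population. When no paired second task is
#' available to estimate it from cross-task correlated activity, it is taken
#' as the normalized mean population vector over the lowest-decile speed
#' epochs, which isolates the same low-arousal activity pattern.
#'
#' @param sess a [session()], or a numeric matrix units x bins of activity.
#' @param behavior required when `sess` is a matrix and the global mode is
#'   estimated from speed; a [behavior_trace()].
#' @param rate_sigma smoothing SD (s) for the rates (default 0.05).
#' @param global_mode `NULL` to estimate from low-speed epochs, a numeric
#'   unit vector to impose one, or `FALSE` to skip removal.
#' @return object of class `population_matrix`: list with `activity`
#'   (normalized matrix), `global_mode`, `kept_units` (indices of non-silent
#'   units), `dt`.
#' @export
preprocess_population <- function(sess, behavior = NULL, rate_sigma = 0.05,
                                  global_mode = NULL) {
  if (inherits(sess, "session")) {
    behavior <- sess$behavior
    n <- length(behavior)
    act <- t(vapply(sess$units, function(u)
      instantaneous_rate(u, sess$duration, behavior$dt, rate_sigma),
      numeric(n)))
  } else {
    act <- sess
  }
  if (nrow(act) < 2) stopf("need at least 2 units")
  dt <- if (!is.null(behavior)) behavior$dt else 0.01
  sds <- apply(act, 1L, stats::sd)
  kept <- which(sds > 0)
  if (length(kept) < nrow(act))
    message(sprintf("excluding %d silent unit(s)", nrow(act) - length(kept)))
  z <- (act[kept, , drop = FALSE] - rowMeans(act[kept, , drop = FALSE])) /
    sds[kept]
  # column demean and unit norm
  z <- sweep(z, 2L, colMeans(z))
  nrm <- sqrt(colSums(z^2))
  zero_cols <- nrm == 0
  nrm[zero_cols] <- 1
  z <- sweep(z, 2L, nrm, `/`)
  p <- NULL
  if (!isFALSE(global_mode)) {
    if (is.numeric(global_mode)) {
      p <- global_mode / sqrt(sum(global_mode^2))
    } else if (!is.null(behavior)) {
      sp <- speed(behavior)
      low <- sp <= stats::quantile(sp, 0.1)
      pv <- rowMeans(z[, low, drop = FALSE])
      if (sqrt(sum(pv^2)) > 0) p <- pv / sqrt(sum(pv^2))
    }
    if (!is.null(p)) {
      proj <- as.numeric(crossprod(z, p)) # a_t . p per column
      z <- z - outer(p, proj)
    }
  }
  structure(list(activity = z, global_mode = p, kept_units = kept,
                 zero_cols = zero_cols, dt = dt),
            class = "population_matrix")
}

#' @export
print.population_matrix <- function(x, ...) {
  cat(sprintf("<population_matrix> %d units x %d bins%s\n", nrow(x$activity),
              ncol(x$activity),
              if (is.null(x$global_mode)) "" else ", global mode removed"))
  invisible(x)
}

#' Detect trials from the paw velocity
#'
#' Smooths the speed with a Gaussian of 2 s full-width half maximum, divides
#' each time point by the value 2 s earlier, and takes every point where this
#' ratio exceeds `ratio_threshold` and is a local maximum of the ratio trace
#' as a trial center (a transition from quiescence to movement). Each trial
#' spans 8 s before to 8 s after its center (1601 bins at 10 ms); centers
#' whose window does not fit in the session are dropped.
#'
#' @param behavior a [behavior_trace()].
#' @param fwhm smoothing full-width half maximum in seconds (default 2).
#' @param ratio_threshold minimum velocity ratio (default 2).
#' @param half_window trial half width in seconds (default 8).
#' @return object of class `trial_set`: list with `centers` (s),
#'   `half_window`, `bins_per_trial`.
#' @export
detect_trials <- function(behavior, fwhm = 2, ratio_threshold = 2,
                          half_window = 8) {
  stopifnot(inherits(behavior, "behavior_trace"))
  dt <- behavior$dt
  n <- length(behavior)
  if (n * dt <= 2 * half_window) stopf("session must be longer than %g s", 2 * half_window)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  vf <- gaussian_smooth(speed(behavior), sigma, dt)
  vf <- pmax(vf, .Machine$double.eps)
  k2 <- round(2 / dt)
  ratio <- rep(NA_real_, n)
  ratio[(k2 + 1L):n] <- vf[(k2 + 1L):n] / vf[1L:(n - k2)]
  idx <- which(ratio > ratio_threshold)
  idx <- idx[idx > 1L & idx < n]
  is_max <- !is.na(ratio[idx - 1L]) & !is.na(ratio[idx + 1L]) &
    ratio[idx] >= ratio[idx - 1L] & ratio[idx] > ratio[idx + 1L]
  centers <- (idx[is_max] - 1L) * dt + behavior$t0
  hw_bins <- round(half_window / dt)
  fit <- (idx[is_max] - 1L) >= hw_bins & (idx[is_max] - 1L) < n - hw_bins
  structure(list(centers = centers[fit], half_window = half_window,
                 bins_per_trial = 2L * hw_bins + 1L, dt = dt),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials, +-%g s (%d bins)\n", length(x$centers),
              x$half_window, x$bins_per_trial))
  invisible(x)
}

#' Mean within-trial population correlation matrix
#'
#' For each trial, the scalar products between the normalized population
#' vectors at all pairs of time points within the trial window are computed
#' (1601 x 1601 at the defaults) and averaged across trials.
#'
#' @param pop a [preprocess_population()] result.
#' @param trials a [detect_trials()] result with >= 1 trial.
#' @return symmetric matrix `bins_per_trial x bins_per_trial`.
#' @export
trial_correlation_matrix <- function(pop, trials) {
  stopifnot(inherits(pop, "population_matrix"), inherits(trials, "trial_set"))
  if (!length(trials$centers)) stopf("no trials to correlate")
  hw <- (trials$bins_per_trial - 1L) %/% 2L
  dt <- pop$dt
  acc <- matrix(0, trials$bins_per_trial, trials$bins_per_trial)
  for (ct in trials$centers) {
    c_bin <- round(ct / dt) + 1L
    idx <- (c_bin - hw):(c_bin + hw)
    a <- pop$activity[, idx, drop = FALSE]
    acc <- acc + crossprod(a)
  }
  acc / length(trials$centers)
}

#' Exponential decay fit of the population correlation
#'
#' Fits `C(delta) = A * exp(-delta / tau)` by nonlinear least squares
#' (Gaussian cost) to the correlation as a function of the absolute temporal
#' distance from a reference bin.
#'
#' @param corr_row correlations at increasing distance from the reference
#'   (e.g. one row of the trial correlation matrix re-indexed by |distance|),
#'   or a full correlation matrix together with `ref_bin`.
#' @param ref_bin when `corr_row` is a matrix: the reference bin index.
#' @param dt bin width in seconds.
#' @param max_delta largest distance (s) used in the fit (default 4).
#' @param tau_bounds,amp_bounds parameter bounds (defaults 0.01..20 s and
#'   0..1.5).
#' @return object of class `decay_fit`: list with `tau` (s), `amplitude`,
#'   `residual` (RMS), `converged`.
#' @export
fit_decay <- function(corr_row, ref_bin = NULL, dt = 0.01, max_delta = 4,
                      tau_bounds = c(0.01, 20), amp_bounds = c(0, 1.5)) {
  if (is.matrix(corr_row)) {
    stopifnot(!is.null(ref_bin))
    nb <- ncol(corr_row)
    deltas <- abs(seq_len(nb) - ref_bin) * dt
    cc <- corr_row[ref_bin, ]
    agg <- tapply(cc, deltas, mean, na.rm = TRUE)
    delta <- as.numeric(names(agg))
    cc <- as.numeric(agg)
  } else {
    cc <- corr_row
    delta <- (seq_along(cc) - 1L) * dt
  }
  keep <- is.finite(cc) & delta <= max_delta
  delta <- delta[keep]; cc <- cc[keep]
  if (length(unique(delta)) < 10) stopf("need >= 10 distinct distance bins")
  if (all(cc <= 0)) {
    warnf("no positive correlations; decay fit failed")
    return(structure(list(tau = NA_real_, amplitude = NA_real_,
                          residual = NA_real_, converged = FALSE),
                     class = "decay_fit"))
  }
  A0 <- min(max(cc[which.min(delta)], 0.05), amp_bounds[2])
  below <- which(cc < A0 * exp(-1))
  tau0 <- if (length(below)) max(delta[below[1L]], tau_bounds[1]) else
    stats::median(delta)
  tau0 <- min(max(tau0, tau_bounds[1]), tau_bounds[2])
  df <- data.frame(delta = delta, cc = cc)
  fit <- tryCatch(
    minpack.lm::nlsLM(cc ~ A * exp(-delta / tau), data = df,
                      start = list(A = A0, tau = tau0),
                      lower = c(amp_bounds[1], tau_bounds[1]),
                      upper = c(amp_bounds[2], tau_bounds[2]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(tau = NA_real_, amplitude = NA_real_,
                          residual = NA_real_, converged = FALSE),
                     class = "decay_fit"))
  est <- stats::coef(fit)
  structure(list(tau = unname(est["tau"]), amplitude = unname(est["A"]),
                 residual = sqrt(mean(stats::resid(fit)^2)), converged = TRUE),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> tau = %.3f s, A = %.3f (RMS resid %.3g)\n",
              x$tau, x$amplitude, x$residual))
  invisible(x)
}

#' Time course of the population-correlation time constant across a trial
#'
#' Fits the exponential decay at each reference bin of the mean within-trial
#' correlation matrix and extracts the time constants at the premovement
#' (-1 s) and movement (+1 s) time points, plus the drop of the movement
#' time constant relative to the median across the trial.
#'
#' @param corr_mat mean correlation matrix from
#'   [trial_correlation_matrix()].
#' @param dt bin width in seconds.
#' @param step fit the decay every `step` bins (default 25, i.e. 0.25 s) to
#'   keep the timecourse cheap; the premove/move bins are always included.
#' @param ... passed to [fit_decay()].
#' @return list with `time` (s relative to the trial center), `tau` (vector),
#'   `tau_premove`, `tau_move`, `drop_move` (tau_move minus the median tau).
#' @export
decay_timecourse <- function(corr_mat, dt = 0.01, step = 25L, ...) {
  nb <- ncol(corr_mat)
  center <- (nb + 1L) %/% 2L
  refs <- unique(sort(c(seq(1L, nb, by = step),
                        center - round(1 / dt), center + round(1 / dt))))
  refs <- refs[refs >= 1L & refs <= nb]
  taus <- vapply(refs, function(r) fit_decay(corr_mat, ref_bin = r, dt = dt, ...)$tau,
                 0)
  tau_pre <- taus[refs == center - round(1 / dt)]
  tau_mov <- taus[refs == center + round(1 / dt)]
  list(time = (refs - center) * dt, tau = taus,
       tau_premove = tau_pre, tau_move = tau_mov,
       drop_move = tau_mov - stats::median(taus, na.rm = TRUE))
}

#' First-order low-pass amplitude gain at a given frequency
#'
#' Gain `1 / sqrt(1 + (2 pi f tau)^2)` of a first-order low-pass filter with
#' time constant `tau`. At `f = 1/tau` the gain is about 16%, which is the
#' sense in which the reciprocal of a population-correlation time constant
#' maps to a frequency.
#'
#' @param f frequency in Hz.
#' @param tau time constant in seconds.
#' @export
lowpass_gain <- function(f, tau) 1 / sqrt(1 + (2 * pi * f * tau)^2)

#' Instantaneous behavioral frequency of a velocity trace
#'
#' For each time point, the smallest low-pass cutoff on a grid of band
#' centers whose local reconstruction error (RMS difference between the
#' speed and its Gaussian-smoothed version, measured in a window inversely
#' proportional to the cutoff) stays within the tracking-noise SD. This is
#' the maximum frequency needed to describe the behavior within the error
#' bounds of the tracking.
#'
#' @param behavior a [behavior_trace()] with a `tracking_noise_sd`.
#' @param freq_grid ascending candidate cutoffs in Hz (default: the default
#'   band-table centers).
#' @return numeric vector of frequencies (Hz) per time bin; points whose
#'   error exceeds the tracking noise even at the highest cutoff get the
#'   highest cutoff.
#' @export
behavior_frequency <- function(behavior,
                               freq_grid = sort(vapply(default_bands(),
                                                       `[[`, 0, "center_freq"))) {
  stopifnot(inherits(behavior, "behavior_trace"))
  noise <- behavior$tracking_noise_sd
  if (noise <= 0) stopf("behavior has no tracking_noise_sd to bound the error")
  sp <- speed(behavior)
  dt <- behavior$dt
  out <- rep(freq_grid[length(freq_grid)], length(sp))
  assigned <- rep(FALSE, length(sp))
  for (f in rev(freq_grid)) { # coarsest last so the smallest adequate f wins
    sm <- gaussian_smooth(sp, 1 / (2 * pi * f), dt)
    err2 <- gaussian_smooth((sp - sm)^2, max(1 / f, 2 * dt), dt)
    ok <- sqrt(pmax(err2, 0)) <= noise
    out[ok] <- f
    assigned <- assigned | ok
  }
  out
}
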