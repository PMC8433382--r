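# Activity-weighted distributions (AWD) and the per-unit velocity-modulation
# metrics derived from them: modulation curve, duration, lag, modulated flag,
# planning-sensory index and the segment bootstrap of the duration.

#' Gaussian-smoothed instantaneous firing rate
#'
#' Bins the spike train on a uniform grid and convolves the counts/dt with a
#' Gaussian kernel (SD 50 ms by default). The integral of the returned trace
#' approximates the spike count.
#'
#' @param unit a [sorted_unit()] or a numeric vector of spike times.
#' @param duration trace length in seconds.
#' @param dt bin width in seconds (default 0.01).
#' @param sigma smoothing SD in seconds (default 0.05); 0 returns the raw
#'   binned rate (counts/dt) without smoothing.
#' @return numeric vector of rates (Hz), length `round(duration/dt)`.
#' @export
instantaneous_rate <- function(unit, duration, dt = 0.01, sigma = 0.05) {
  st <- if (inherits(unit, "sorted_unit")) unit$spike_times else sort(unit)
  n <- round(duration / dt)
  if (!length(st)) return(numeric(n))
  counts <- tabulate(pmin(n, floor(st / dt) + 1L), n)
  if (sigma == 0) return(counts / dt)
  gaussian_smooth(counts / dt, sigma, dt)
}

#' Activity-weighted distribution (AWD) of activity versus speed
#'
#' Generalizes the spike-triggered average: the observed speed range is
#' divided into `n_bins` equally sized bins and, for every temporal lag in
#' `±max_lag` (10 ms steps), the mean continuous activity at that lag
#' relative to the behavior sample is computed per speed bin. Negative lags
#' mean the activity precedes the movement. The per-bin mean activity over
#' lags 3 to 4 s serves as baseline. Cells with no occupancy are `NA` and
#' excluded from all means.
#'
#' @param activity continuous activity trace on the behavior's grid (e.g.
#'   from [instantaneous_rate()]).
#' @param behavior a [behavior_trace()], or a numeric vector already holding
#'   the behavioral variable (speed, one velocity axis, or position).
#' @param dt sample spacing in seconds (taken from `behavior` if a trace).
#' @param max_lag lag range half width in seconds (default 4).
#' @param n_bins number of behavioral bins (default 10).
#' @param bin_edges optional fixed bin edges (length `n_bins + 1`), e.g. to
#'   reuse whole-session edges for segment AWDs.
#' @return object of class `awd_table`: list with `values` (lags x bins
#'   matrix of mean activity), `lags`, `bin_edges`, `baseline` (per bin) and
#'   occupancy sums used for recombination.
#' @export
compute_awd <- function(activity, behavior, dt = NULL, max_lag = 4,
                        n_bins = 10, bin_edges = NULL) {
  if (inherits(behavior, "behavior_trace")) {
    beh <- speed(behavior)
    dt <- behavior$dt
  } else {
    beh <- behavior
    if (is.null(dt)) dt <- 0.01
  }
  n <- length(beh)
  stopifnot(length(activity) == n)
  if (is.null(bin_edges)) {
    rng <- range(beh)
    if (diff(rng) == 0) stopf("behavioral variable is constant: degenerate binning")
    bin_edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  n_bins <- length(bin_edges) - 1L
  bin <- cut(beh, bin_edges, include.lowest = TRUE, labels = FALSE)
  bin[is.na(bin)] <- NA_integer_ # out-of-range values (fixed edges) excluded
  L <- round(max_lag / dt)
  num <- den <- matrix(0, 2L * L + 1L, n_bins)
  for (b in seq_len(n_bins)) {
    ind <- as.numeric(!is.na(bin) & bin == b)
    if (!any(ind > 0)) next
    num[, b] <- xcorr_sums(ind, activity, L)
    den[, b] <- xcorr_sums(ind, rep(1, n), L)
  }
  values <- num / den
  values[den == 0] <- NA_real_
  lags <- seq(-L, L) * dt
  base_rows <- lags >= 3 & lags <= 4
  baseline <- colMeans(values[base_rows, , drop = FALSE], na.rm = TRUE)
  structure(list(values = values, lags = lags, bin_edges = bin_edges,
                 baseline = baseline, num = num, den = den, dt = dt),
            class = "awd_table")
}

#' @export
print.awd_table <- function(x, ...) {
  cat(sprintf("<awd_table> %d lags x %d bins, lag range %.2f..%.2f s\n",
              nrow(x$values), ncol(x$values), min(x$lags), max(x$lags)))
  invisible(x)
}

# Per-lag modulation: mean over bins of |AWD - baseline|, NA cells excluded.
# By default bins are weighted by their occupancy, which makes the curve the
# time average of the absolute baseline-subtracted tuning and keeps the
# sparsely visited extreme-speed bins from dominating the estimator noise;
# weight_bins = FALSE gives the plain unweighted mean over bins.
#' @keywords internal
#' @noRd
awd_modulation_curve <- function(awd, weight_bins = TRUE) {
  dev <- abs(sweep(awd$values, 2L, awd$baseline))
  if (!weight_bins) return(rowMeans(dev, na.rm = TRUE))
  w <- awd$den
  w[is.na(awd$values)] <- 0
  dev[is.na(dev)] <- 0
  rowSums(dev * w) / pmax(rowSums(w), 1)
}

#' Velocity-modulation metrics of an AWD table
#'
#' Computes the per-lag modulation curve (mean absolute baseline-subtracted
#' AWD), finds its global peak, and traces backward and forward from the peak
#' until the modulation falls below 80% of the peak (crossings linearly
#' interpolated). The duration is the time between the two crossings, the
#' temporal lag their midpoint. The normalized curve subtracts the mean and
#' divides by the SD of the modulation over the extreme lags (-4 to -3 and
#' 3 to 4 s); a unit is modulated when the normalized curve exceeds 10.
#'
#' @param awd an [compute_awd()] table.
#' @param peak_frac crossing threshold as a fraction of the peak
#'   (default 0.8).
#' @param mod_criterion normalized-modulation threshold for the `modulated`
#'   flag (default 10).
#' @param weight_bins weight the per-lag mean over speed bins by bin
#'   occupancy (default TRUE); FALSE averages all occupied bins equally.
#'   Occupancy weighting turns the curve into a time average and keeps the
#'   rarely visited top-speed bins from dominating the estimator noise.
#' @return object of class `modulation_profile`: list with `modulation`,
#'   `normalized`, `lags`, `peak_value`, `duration`, `lag`, `modulated`,
#'   `capped` (TRUE when a crossing ran into the lag boundary).
#' @export
modulation_metrics <- function(awd, peak_frac = 0.8, mod_criterion = 10,
                               weight_bins = TRUE) {
  stopifnot(inherits(awd, "awd_table"))
  m <- awd_modulation_curve(awd, weight_bins)
  lags <- awd$lags
  ext <- (lags >= 3 & lags <= 4) | (lags >= -4 & lags <= -3)
  mu <- mean(m[ext]); sdv <- stats::sd(m[ext])
  normalized <- if (sdv > 0) (m - mu) / sdv else m * 0
  ipk <- which.max(m)
  peak <- m[ipk]
  thr <- peak_frac * peak
  dt <- awd$dt
  capped <- FALSE
  if (peak == 0 || !is.finite(peak)) {
    res <- list(duration = (length(lags) - 1) * dt, lag = 0, capped = TRUE)
  } else {
    # backward crossing
    j <- ipk
    while (j > 1L && m[j - 1L] >= thr) j <- j - 1L
    if (j == 1L) { t_back <- lags[1L]; capped <- TRUE }
    else t_back <- lags[j] - dt * (m[j] - thr) / (m[j] - m[j - 1L])
    # forward crossing
    k <- ipk
    nl <- length(lags)
    while (k < nl && m[k + 1L] >= thr) k <- k + 1L
    if (k == nl) { t_fwd <- lags[nl]; capped <- TRUE }
    else t_fwd <- lags[k] + dt * (m[k] - thr) / (m[k] - m[k + 1L])
    res <- list(duration = t_fwd - t_back, lag = (t_fwd + t_back) / 2,
                capped = capped)
  }
  structure(list(modulation = m, normalized = normalized, lags = lags,
                 peak_value = peak, duration = res$duration, lag = res$lag,
                 modulated = is.finite(sdv) && sdv > 0 &&
                   max(normalized) > mod_criterion,
                 capped = res$capped),
            class = "modulation_profile")
}

#' @export
print.modulation_profile <- function(x, ...) {
  cat(sprintf("<modulation_profile> peak %.3g, duration %.3f s, lag %+.3f s, %smodulated%s\n",
              x$peak_value, x$duration, x$lag,
              if (x$modulated) "" else "not ", if (x$capped) " (capped)" else ""))
  invisible(x)
}

#' Planning-sensory index of a modulation profile
#'
#' Normalized difference between the summed velocity modulation at planning
#' lags (-1.1 to -0.1 s) and at sensory-integration lags (0 to 1 s):
#' `100 * (P - S) / (P + S)`. Positive values indicate dominant planning
#' (pre-movement) modulation, negative values dominant sensory (post-
#' movement) modulation.
#'
#' @param profile a [modulation_metrics()] result covering at least
#'   -1.1 to 1 s.
#' @param planning_window,sensory_window lag windows in seconds.
#' @return percentage in -100..100 (`NaN` with a warning when both sums
#'   are zero).
#' @export
planning_sensory_index <- function(profile,
                                   planning_window = c(-1.1, -0.1),
                                   sensory_window = c(0, 1)) {
  stopifnot(inherits(profile, "modulation_profile"))
  lg <- profile$lags
  if (min(lg) > planning_window[1] || max(lg) < sensory_window[2])
    stopf("profile must cover lags %g to %g s", planning_window[1], sensory_window[2])
  P <- sum(profile$modulation[lg >= planning_window[1] & lg <= planning_window[2]])
  S <- sum(profile$modulation[lg >= sensory_window[1] & lg <= sensory_window[2]])
  if (P + S == 0) {
    warnf("planning and sensory modulation both zero; index undefined")
    return(NaN)
  }
  100 * (P - S) / (P + S)
}

#' Segment bootstrap of the modulation duration
#'
#' Splits the session into `n_segments` contiguous equal segments, computes
#' the AWD occupancy sums per segment (with the whole-session bin edges),
#' resamples segments with replacement `n_reps` times, recombines the
#' resampled sums into one AWD (occupancy-weighted, i.e. the AWD of the
#' concatenated resample) and recomputes the modulation duration. Returns the
#' SD across repetitions.
#'
#' @param activity,behavior as in [compute_awd()].
#' @param n_segments number of segments (default 100; sessions shorter than
#'   `10 * n_segments` seconds trigger a warning).
#' @param n_reps bootstrap repetitions (default 100).
#' @param seed integer seed.
#' @param ... further arguments passed to [compute_awd()].
#' @return list with `sd` (bootstrap SD of the duration in seconds),
#'   `mean` and the vector of per-repetition `durations`.
#' @export
bootstrap_duration <- function(activity, behavior, n_segments = 100,
                               n_reps = 100, seed = 1, ...) {
  if (n_segments < 2) stopf("n_segments must be >= 2")
  if (inherits(behavior, "behavior_trace")) {
    beh <- speed(behavior); dt <- behavior$dt
  } else {
    beh <- behavior; dt <- 0.01
  }
  n <- length(beh)
  if (n * dt < 10 * n_segments)
    warnf("session (%.0f s) shorter than 10 s per segment", n * dt)
  set.seed(as.integer(seed))
  edges <- seq(min(beh), max(beh), length.out = 11L)
  if (diff(range(beh)) == 0) stopf("behavioral variable is constant")
  bounds <- floor(seq(0, n, length.out = n_segments + 1L))
  seg_awd <- lapply(seq_len(n_segments), function(s) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    compute_awd(activity[idx], beh[idx], dt = dt, bin_edges = edges, ...)
  })
  template <- seg_awd[[1L]]
  durations <- vapply(seq_len(n_reps), function(r) {
    pick <- sample.int(n_segments, n_segments, replace = TRUE)
    num <- Reduce(`+`, lapply(seg_awd[pick], `[[`, "num"))
    den <- Reduce(`+`, lapply(seg_awd[pick], `[[`, "den"))
    values <- num / den
    values[den == 0] <- NA_real_
    awd <- template
    awd$values <- values
    awd$num <- num
    awd$den <- den
    base_rows <- awd$lags >= 3 & awd$lags <= 4
    awd$baseline <- colMeans(values[base_rows, , drop = FALSE], na.rm = TRUE)
    modulation_metrics(awd)$duration
  }, 0)
  list(sd = stats::sd(durations), mean = mean(durations), durations = durations)
}
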