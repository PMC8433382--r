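# Threshold-based snippet extraction and seed-and-neighborhood spike sorting
# in the raw 76-dimensional waveform space, plus the mu-rate decorrelation
# metric.

#' Spike snippet container
#'
#' @param waveforms numeric matrix `n x 76` (microvolts); each row's minimum
#'   must sit at the peak-alignment sample.
#' @param peak_times trough times in seconds, one per row.
#' @param threshold detection threshold in microvolts (negative).
#' @param fs sampling rate in Hz.
#' @param peak_sample alignment sample of the trough (default 16).
#' @return object of class `spike_snippets`.
#' @export
spike_snippets <- function(waveforms, peak_times, threshold, fs = 30000,
                           peak_sample = 16L) {
  if (!is.matrix(waveforms)) waveforms <- matrix(waveforms, nrow = 0, ncol = 76)
  stopifnot(nrow(waveforms) == length(peak_times))
  structure(list(waveforms = waveforms, peak_times = peak_times,
                 threshold = threshold, fs = fs, peak_sample = peak_sample),
            class = "spike_snippets")
}

#' @export
print.spike_snippets <- function(x, ...) {
  cat(sprintf("<spike_snippets> %d snippets of %d samples (threshold %.1f uV)\n",
              nrow(x$waveforms), ncol(x$waveforms), x$threshold))
  invisible(x)
}

#' Sorted unit container
#'
#' @param spike_times strictly increasing spike times in seconds.
#' @param mean_waveform optional mean waveform (76 samples).
#' @param unit_class "SU" or "MU".
#' @param area cortical area label.
#' @param duration session duration in seconds (for the firing rate).
#' @return object of class `sorted_unit` with a `firing_rate` field.
#' @export
sorted_unit <- function(spike_times, mean_waveform = NULL, unit_class = "MU",
                        area = "M1", duration = NA_real_) {
  spike_times <- sort(unname(spike_times))
  if (anyDuplicated(spike_times)) spike_times <- unique(spike_times)
  structure(list(spike_times = spike_times, mean_waveform = mean_waveform,
                 unit_class = unit_class, area = area, duration = duration,
                 firing_rate = if (is.na(duration)) NA_real_ else
                   length(spike_times) / duration),
            class = "sorted_unit")
}

#' @export
print.sorted_unit <- function(x, ...) {
  cat(sprintf("<sorted_unit> %s (%s), %d spikes, %.2f Hz\n", x$unit_class,
              x$area, length(x$spike_times), x$firing_rate))
  invisible(x)
}

#' Extract threshold-crossing spike snippets from a raw trace
#'
#' The trace is (optionally) high-pass filtered at 300 Hz, the detection
#' threshold is set to minus four times the filtered trace's SD, and every
#' local minimum below threshold yields a peak-aligned window from -0.5 to
#' +2 ms around the trough (76 samples at 30 kHz; recomputed from the ms
#' bounds with a warning at other sampling rates). Candidate troughs closer
#' than one window are resolved to the deeper trough.
#'
#' @param raw a [raw_trace()].
#' @param highpass apply the 300 Hz Butterworth high-pass first
#'   (default TRUE; set FALSE if the trace is already filtered).
#' @param threshold_sd threshold in SD units (default 4).
#' @return a [spike_snippets()].
#' @export
extract_snippets <- function(raw, highpass = TRUE, threshold_sd = 4) {
  stopifnot(inherits(raw, "raw_trace"))
  fs <- raw$fs
  pre <- round(0.0005 * fs)
  post <- round(0.002 * fs)
  if (fs != 30000)
    warnf("fs = %g Hz: window recomputed from -0.5/+2 ms bounds (%d samples)",
          fs, pre + post + 1L)
  v <- raw$voltage
  if (highpass && length(v) > 18L) v <- butter_highpass_zerophase(v, fs, 300)
  wlen <- pre + post + 1L
  thr <- -threshold_sd * stats::sd(v)
  n <- length(v)
  if (n < wlen)
    return(spike_snippets(matrix(0, 0, wlen), numeric(), thr, fs, pre + 1L))
  # local minima below threshold (negative peaks only)
  cand <- which(v < thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[v[cand] <= v[cand - 1L] & v[cand] < v[cand + 1L]]
  cand <- cand[cand > pre & cand <= n - post]
  if (!length(cand))
    return(spike_snippets(matrix(0, 0, wlen), numeric(), thr, fs, pre + 1L))
  # overlapping windows: keep the deeper trough
  keep <- logical(length(cand))
  ord <- order(v[cand]) # deepest first
  taken <- rep(FALSE, n)
  for (i in ord) {
    lo <- max(1L, cand[i] - wlen + 1L)
    hi <- min(n, cand[i] + wlen - 1L)
    if (!any(taken[lo:hi])) {
      keep[i] <- TRUE
      taken[cand[i]] <- TRUE
    }
  }
  cand <- sort(cand[keep])
  wf <- t(vapply(cand, function(p) v[(p - pre):(p + post)], numeric(wlen)))
  spike_snippets(wf, cand / fs, thr, fs, pre + 1L)
}

# Noise level of a snippet set: SD across snippets of the value at the sample
# 0.5 ms before the trough (outside the spike by refractoriness, so it
# measures recording noise rather than waveform variability of the unit).
#' @keywords internal
#' @noRd
snippet_noise_level <- function(wf, peak_sample, fs) {
  s <- max(1L, peak_sample - round(0.0005 * fs))
  stats::sd(wf[, s])
}

#' Seed-and-neighborhood spike sorting
#'
#' Iteratively extracts units from the snippet set in the raw 76-dimensional
#' waveform space: (1) estimate the noise level from the variability 0.5 ms
#' before the trough; (2) among `n_candidates` randomly drawn snippets, take
#' the one with the most neighbors within the noise radius as seed; (3)
#' alternately recompute the neighborhood's noise level, radius and mean
#' waveform until membership is stable; (4) remove the members and repeat;
#' (5) stop when the next unit's rate falls below `min_rate`.
#'
#' The cluster size is dictated by the noise level: a snippet is a neighbor
#' of a cluster center when its squared distance is consistent with pure
#' per-sample noise of SD `sigma`, i.e. within
#' `sigma * sqrt(qchisq(1 - alpha, 76))` (about `1.4 * sqrt(76) * sigma` at
#' the default `alpha = 1e-6`); for snippet-to-snippet distances in the seed
#' search the radius is `sqrt(2)` larger because both snippets carry noise.
#' `radius_mode = "box"` instead requires every sample to be within
#' `4 * sigma` of the center.
#'
#' @param snippets a [spike_snippets()].
#' @param duration session duration in seconds (for the 0.1 Hz stop rule).
#' @param n_candidates random seed candidates per unit (default 500, or all
#'   snippets if fewer).
#' @param min_rate stop rule rate in Hz (default 0.1).
#' @param max_iter refinement rounds before accepting the last membership
#'   with a flag (default 50).
#' @param radius_mode "ball" (default) or "box".
#' @param alpha tail probability of the chi-squared noise-consistency radius
#'   (default 1e-6).
#' @param seed integer seed for the candidate draws.
#' @return list of [sorted_unit()]s (attribute `assignment` maps each snippet
#'   to a unit index, 0 = unassigned; attribute `flagged` marks units that
#'   hit `max_iter`).
#' @export
sort_snippets <- function(snippets, duration, n_candidates = 500L,
                          min_rate = 0.1, max_iter = 50L,
                          radius_mode = c("ball", "box"), alpha = 1e-6,
                          seed = 1) {
  stopifnot(inherits(snippets, "spike_snippets"))
  radius_mode <- match.arg(radius_mode)
  set.seed(as.integer(seed))
  wf <- snippets$waveforms
  n_all <- nrow(wf)
  if (n_all < 1) stopf("need at least one snippet")
  dim76 <- ncol(wf)
  chi_r <- sqrt(stats::qchisq(1 - alpha, dim76)) # noise-consistency radius, sigma units
  remaining <- seq_len(n_all)
  assignment <- integer(n_all)
  units <- list()
  flagged <- logical()

  members_of <- function(center, sigma, rows, pairwise = FALSE) {
    d <- wf[rows, , drop = FALSE] -
      matrix(center, length(rows), dim76, byrow = TRUE)
    scale <- if (pairwise) sqrt(2) else 1 # both points noisy in the seed search
    if (radius_mode == "ball")
      rows[sqrt(rowSums(d^2)) <= scale * sigma * chi_r]
    else rows[apply(abs(d) <= scale * 4 * sigma, 1L, all)]
  }

  repeat {
    if (length(remaining) < 1) break
    noise <- snippet_noise_level(wf[remaining, , drop = FALSE],
                                 snippets$peak_sample, snippets$fs)
    if (!is.finite(noise) || noise == 0) noise <- .Machine$double.eps
    cand <- if (length(remaining) > n_candidates)
      sample(remaining, n_candidates) else remaining
    counts <- vapply(cand, function(i)
      length(members_of(wf[i, ], noise, remaining, pairwise = TRUE)), 0L)
    # tie-break: lowest snippet index among equal neighbor counts
    best <- cand[order(-counts, cand)][1L]
    mem <- members_of(wf[best, ], noise, remaining, pairwise = TRUE)
    flag <- FALSE
    for (it in seq_len(max_iter)) {
      noise_u <- snippet_noise_level(wf[mem, , drop = FALSE],
                                     snippets$peak_sample, snippets$fs)
      if (!is.finite(noise_u) || noise_u == 0) noise_u <- noise
      center <- colMeans(wf[mem, , drop = FALSE])
      new_mem <- members_of(center, noise_u, remaining)
      if (length(new_mem) == 0) new_mem <- mem
      if (identical(sort(new_mem), sort(mem))) break
      mem <- new_mem
      if (it == max_iter) flag <- TRUE
    }
    rate <- length(mem) / duration
    if (rate < min_rate) break
    st <- snippets$peak_times[mem]
    u <- classify_unit(sorted_unit(st,
                                   mean_waveform = colMeans(wf[mem, , drop = FALSE]),
                                   duration = duration))
    units[[length(units) + 1L]] <- u
    flagged <- c(flagged, flag)
    assignment[mem] <- length(units)
    remaining <- setdiff(remaining, mem)
  }
  structure(units, assignment = assignment, flagged = flagged)
}

#' Classify a unit as single unit (SU) or multiunit (MU)
#'
#' A unit is a single unit when its conditional firing rate in the 2 ms
#' window following each spike (number of inter-spike intervals below 2 ms
#' divided by spike count times 2 ms) is smaller than its average firing
#' rate: a refractory neuron fires less right after a spike than on average,
#' while a mixture of neurons does not.
#'
#' @param unit a [sorted_unit()] with a known duration.
#' @param refractory ISI criterion in seconds (default 0.002).
#' @return the unit with `unit_class` set.
#' @export
classify_unit <- function(unit, refractory = 0.002) {
  stopifnot(inherits(unit, "sorted_unit"))
  n <- length(unit$spike_times)
  if (n < 2 || is.na(unit$duration)) {
    unit$unit_class <- "SU"
    return(unit)
  }
  short <- sum(diff(unit$spike_times) < refractory)
  isi_rate <- short / (n * refractory)
  unit$unit_class <- if (isi_rate < unit$firing_rate) "SU" else "MU"
  unit
}

#' Cross-correlogram floor between two units (mu-rate)
#'
#' Builds the spike-triggered rate of unit B around the spikes of unit A over
#' lags -10 to 10 s in 10 ms bins, takes the minimum over lags, and expresses
#' it as a percentage of unit B's average rate. Independent (decorrelated)
#' firing gives values near 100%; a lag at which B never fires relative to A
#' gives 0%.
#'
#' @param unit_a,unit_b two distinct [sorted_unit()]s with >= 1 spike each.
#' @param duration session duration in seconds.
#' @param max_lag correlogram half width in seconds (default 10).
#' @param bin correlogram bin width in seconds (default 0.01).
#' @return mu-rate percentage (scalar).
#' @export
mu_rate <- function(unit_a, unit_b, duration, max_lag = 10, bin = 0.01) {
  stopifnot(inherits(unit_a, "sorted_unit"), inherits(unit_b, "sorted_unit"))
  if (identical(unit_a$spike_times, unit_b$spike_times))
    stopf("mu_rate is undefined for a unit against itself")
  ta <- unit_a$spike_times; tb <- unit_b$spike_times
  if (!length(ta) || !length(tb)) stopf("both units need at least one spike")
  # binned cross-correlogram via FFT on the 10 ms grid
  nb <- ceiling(duration / bin)
  ca <- tabulate(pmin(nb, floor(ta / bin) + 1L), nb)
  cb <- tabulate(pmin(nb, floor(tb / bin) + 1L), nb)
  L <- round(max_lag / bin)
  counts <- xcorr_sums(ca, cb, L) # sum_t a(t) b(t+lag)
  n_trig <- xcorr_sums(ca, rep(1, nb), L) # triggers with a valid lag bin
  rate_b <- counts / pmax(n_trig, 1) / bin
  100 * min(rate_b) / (length(tb) / duration)
}
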