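# Synthetic single-channel 30 kHz voltage traces: spike-waveform templates
# embedded at Poisson times in white noise, with ground truth retained.

#' Raw voltage trace container
#'
#' @param voltage numeric vector of samples in microvolts.
#' @param fs sampling rate in Hz (30000 for the standard acquisition chain).
#' @param ground_truth optional data.frame with columns `template_id` and
#'   `peak_time` (s) recording embedded spikes.
#' @return object of class `raw_trace`.
#' @export
raw_trace <- function(voltage, fs = 30000, ground_truth = NULL) {
  if (!all(is.finite(voltage))) stopf("voltage must be finite")
  structure(list(voltage = voltage, fs = fs, ground_truth = ground_truth),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %.1f s at %g Hz, SD %.1f uV\n",
              length(x$voltage) / x$fs, x$fs, stats::sd(x$voltage)))
  invisible(x)
}

#' Example spike-waveform templates
#'
#' Three biphasic extracellular waveforms (76 samples at 30 kHz, negative
#' peak at sample 16) differing in repolarization width and overshoot, each
#' scaled to a negative peak of -1 (multiply by the desired amplitude).
#'
#' @return list of numeric vectors of length 76.
#' @export
synthetic_templates <- function() {
  t76 <- (seq_len(76L) - 16L) / 30 # ms relative to trough
  shape <- function(w_neg, w_pos, over) {
    v <- -exp(-0.5 * (t76 / w_neg)^2) + over * exp(-0.5 * ((t76 - 3.5 * w_pos) / w_pos)^2)
    v / abs(min(v))
  }
  list(narrow = shape(0.08, 0.12, 0.30),
       broad = shape(0.28, 0.45, 0.20),
       overshoot = shape(0.12, 0.18, 0.90))
}

#' Generate a raw voltage trace with embedded spike templates
#'
#' Each template occurs at homogeneous Poisson times (occurrences of the same
#' template closer than 2 ms are dropped), superimposed on white Gaussian
#' noise. Ground-truth template identities and peak times are stored.
#'
#' @param templates list of 76-sample waveforms (negative peak at sample 16),
#'   in microvolts.
#' @param rates occurrence rates in Hz, one per template (recycled).
#' @param noise_sd white noise SD in microvolts.
#' @param duration trace length in seconds.
#' @param fs sampling rate in Hz (default 30000).
#' @param seed integer seed.
#' @return a [raw_trace()].
#' @export
generate_raw_trace <- function(templates, rates, noise_sd, duration,
                               fs = 30000, seed = 1) {
  for (tp in templates) {
    if (length(tp) != 76L) stopf("templates must have 76 samples")
    if (which.min(tp) != 16L) stopf("template negative peak must be at sample 16")
  }
  set.seed(as.integer(seed))
  n <- round(duration * fs)
  v <- stats::rnorm(n, sd = noise_sd)
  rates <- rep_len(rates, length(templates))
  gt <- list()
  for (i in seq_along(templates)) {
    k <- stats::rpois(1, rates[i] * duration)
    pk <- sort(stats::runif(k, 0.01, duration - 0.01))
    if (length(pk) > 1) pk <- pk[c(TRUE, diff(pk) >= 0.002)]
    for (p in pk) {
      s0 <- round(p * fs) - 15L # window start so the trough lands at round(p*fs)
      idx <- s0:(s0 + 75L)
      ok <- idx >= 1L & idx <= n
      v[idx[ok]] <- v[idx[ok]] + templates[[i]][ok]
    }
    if (length(pk))
      gt[[i]] <- data.frame(template_id = i, peak_time = round(pk * fs) / fs)
  }
  raw_trace(v, fs = fs,
            ground_truth = if (length(gt)) do.call(rbind, gt) else
              data.frame(template_id = integer(), peak_time = numeric()))
}
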