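# Shared fixture builders. Everything is generated in code at test time.

# Homogeneous Poisson spike train as a sorted_unit.
poisson_unit <- function(rate, duration, seed, area = "M1") {
  set.seed(seed)
  n <- rpois(1, rate * duration)
  sorted_unit(sort(runif(n, 0, duration)), area = area, duration = duration)
}

# Session whose units are linearly coupled to the signed velocity components,
# used by the decoder-sweep experiments. Behavior is execution-heavy (mostly
# active, fast heading changes) with sub-movement content near 2.3 Hz.
coupled_session <- function(seed, duration = 600, n_units = 12, gain = 2.5,
                            baseline = 12, submovement_freq = 2.3) {
  beh <- generate_behavior(duration, submovement_freq = submovement_freq,
                           dwell_active = 8, dwell_quiescent = 0.5,
                           direction_tau = 0.15, seed = seed)
  specs <- lapply(seq_len(n_units), function(u)
    unit_spec(lag = 0, modulation_sigma = 0.02, gain = gain,
              baseline_rate = baseline,
              variable = if (u %% 2 == 0) "vx" else "vy"))
  generate_session(beh, specs, seed = seed + 1000)
}

# Raw 30 kHz trace with the three example templates at a given SNR.
template_raw_trace <- function(seed, duration = 300, snr = 8, noise_sd = 20,
                               rates = c(1.5, 1.2, 1.0)) {
  tpl <- lapply(synthetic_templates(), function(w) w * snr * noise_sd)
  generate_raw_trace(tpl, rates = rates, noise_sd = noise_sd,
                     duration = duration, seed = seed)
}

# Brute-force circular lagged least squares: builds the design matrix
# explicitly (wrap-around lags, centered columns) and solves the normal
# equations with base solve(). Oracle for fit_lagged_kernel.
bruteforce_lagged_lsq <- function(X, y, lags) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  yc <- y - mean(y)
  D <- do.call(cbind, lapply(seq_len(ncol(X)), function(j)
    sapply(lags, function(l) Xc[((seq_len(n) - 1L - l) %% n) + 1L, j])))
  w <- solve(crossprod(D), crossprod(D, yc))
  list(weights = matrix(w, length(lags), ncol(X)),
       prediction = as.numeric(D %*% w) + mean(y))
}
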