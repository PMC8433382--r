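test_that("instantaneous rate integrates to the spike count and hits delta cases", {
  dt <- 0.01
  r1 <- instantaneous_rate(c(5), 10, dt)
  expect_equal(sum(r1) * dt, 1, tolerance = 1e-6) # single spike has area 1
  expect_equal(which.max(r1), 501L)
  # two spikes 1 s apart: rate at the midpoint is essentially zero
  r2 <- instantaneous_rate(c(4, 5), 10, dt)
  expect_lt(r2[451], 1e-8)
  # homogeneous Poisson at 10 Hz averages to 10 Hz
  u <- poisson_unit(10, 600, seed = 1)
  expect_lt(abs(mean(instantaneous_rate(u, 600, dt)) - 10), 0.5)
  expect_equal(instantaneous_rate(numeric(0), 5, dt), numeric(500))
})

test_that("constant activity gives a constant AWD and zero modulation", {
  beh <- generate_behavior(120, seed = 2)
  awd <- compute_awd(rep(3, length(beh)), beh)
  expect_true(all(abs(awd$values[!is.na(awd$values)] - 3) < 1e-12))
  prof <- modulation_metrics(awd)
  expect_equal(max(abs(prof$modulation)), 0, tolerance = 1e-12)
  expect_false(prof$modulated)
})

test_that("activity leading the movement peaks at the corresponding negative lag", {
  beh <- generate_behavior(600, seed = 3)
  sp <- speed(beh)
  # planning-like activity: reflects the speed 200 ms in the future
  act_plan <- c(sp[21:length(sp)], rep(sp[length(sp)], 20))
  prof <- modulation_metrics(compute_awd(act_plan, beh))
  expect_lt(abs(prof$lag - (-0.2)), 0.03)
  # sensory-like activity: follows the speed by 200 ms
  act_sens <- c(rep(sp[1], 20), sp[1:(length(sp) - 20)])
  prof2 <- modulation_metrics(compute_awd(act_sens, beh))
  expect_lt(abs(prof2$lag - 0.2), 0.03)
})

test_that("circularly shifted activity stays inside the modulation noise band", {
  beh <- generate_behavior(600, seed = 4)
  sp <- speed(beh)
  shifted <- c(sp[2001:length(sp)], sp[1:2000]) # 20 s circular shift
  prof <- modulation_metrics(compute_awd(shifted, beh))
  expect_false(prof$modulated)
})

test_that("constant speed is a degenerate-binning error", {
  beh <- behavior_trace(rep(3, 1000), rep(4, 1000))
  expect_error(compute_awd(rep(1, 1000), beh), "degenerate|constant")
})

test_that("a Gaussian modulation curve has the closed-form 80% width", {
  # duration = 2 * sigma * sqrt(2 * ln(1/0.8)) for a Gaussian-shaped curve
  dt <- 0.01
  lags <- seq(-4, 4, by = dt)
  sigma_m <- 0.3
  curve <- exp(-0.5 * (lags / sigma_m)^2)
  awd <- structure(list(values = matrix(curve, ncol = 1) + 1,
                        lags = lags, bin_edges = c(0, 1),
                        baseline = 1,
                        num = matrix(curve, ncol = 1),
                        den = matrix(1, length(lags), 1), dt = dt),
                   class = "awd_table")
  prof <- modulation_metrics(awd)
  expect_equal(prof$duration, 2 * sigma_m * sqrt(2 * log(1 / 0.8)),
               tolerance = 1e-3)
  expect_equal(prof$lag, 0, tolerance = 1e-6)
  expect_false(prof$capped)
})

test_that("a flat modulation curve is capped and flagged as unmodulated", {
  dt <- 0.01
  lags <- seq(-4, 4, by = dt)
  awd <- structure(list(values = matrix(2, length(lags), 1),
                        lags = lags, bin_edges = c(0, 1), baseline = 1,
                        num = matrix(1, length(lags), 1),
                        den = matrix(1, length(lags), 1), dt = dt),
                   class = "awd_table")
  prof <- modulation_metrics(awd)
  expect_true(prof$capped)
  expect_equal(prof$duration, 8, tolerance = 1e-9)
  expect_false(prof$modulated)
})

test_that("modulation is invariant to adding a constant to the activity", {
  beh <- generate_behavior(120, seed = 5)
  u <- generate_session(beh, list(unit_spec(lag = -0.1, gain = 2)), seed = 6)
  act <- instantaneous_rate(u$units[[1]], u$duration)
  m1 <- modulation_metrics(compute_awd(act, beh))
  m2 <- modulation_metrics(compute_awd(act + 7, beh))
  expect_equal(m1$modulation, m2$modulation, tolerance = 1e-9)
})

test_that("the AWD of a time-reversed session is the lag-reversed AWD", {
  beh <- generate_behavior(120, seed = 7)
  u <- generate_session(beh, list(unit_spec(lag = -0.2, gain = 2)), seed = 8)
  act <- instantaneous_rate(u$units[[1]], u$duration)
  awd <- compute_awd(act, beh)
  beh_rev <- behavior_trace(rev(beh$vx), rev(beh$vy))
  awd_rev <- compute_awd(rev(act), beh_rev)
  expect_equal(awd_rev$values, awd$values[nrow(awd$values):1, ],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("planning-sensory index hits its one-sided and undefined cases", {
  dt <- 0.01
  lags <- seq(-4, 4, by = dt)
  mk_prof <- function(center) {
    curve <- exp(-0.5 * ((lags - center) / 0.1)^2)
    structure(list(modulation = curve, normalized = curve, lags = lags,
                   peak_value = 1, duration = 0.2, lag = center,
                   modulated = TRUE, capped = FALSE),
              class = "modulation_profile")
  }
  expect_equal(planning_sensory_index(mk_prof(-0.5)), 100, tolerance = 0.5)
  expect_equal(planning_sensory_index(mk_prof(0.5)), -100, tolerance = 0.5)
  flat <- mk_prof(0)
  flat$modulation <- rep(0, length(lags))
  expect_warning(psi <- planning_sensory_index(flat), "undefined")
  expect_true(is.nan(psi))
})

test_that("bootstrap duration SD is tiny for a deterministic noise-free unit", {
  beh <- generate_behavior(300, seed = 9)
  sess <- generate_session(beh, list(unit_spec(lag = -0.1,
                                               modulation_sigma = 0.15,
                                               gain = 3)), seed = 10)
  act <- gaussian_smooth(attr(sess$units[[1]], "true_rate"), 0.05, 0.01)
  expect_warning(bs <- bootstrap_duration(act, beh, n_segments = 50,
                                          n_reps = 30, seed = 1),
                 "shorter")
  prof <- modulation_metrics(compute_awd(act, beh))
  expect_lt(bs$sd / prof$duration, 0.2)
  expect_error(bootstrap_duration(act, beh, n_segments = 1), "n_segments")
})

test_that("bootstrap duration SD shrinks roughly as sqrt(session length)", {
  sds <- vapply(c(600, 2400), function(dur) {
    sd_i <- vapply(1:4, function(s) {
      beh <- generate_behavior(dur, seed = s)
      sess <- generate_session(beh, list(unit_spec(lag = -0.1,
                                                   modulation_sigma = 0.15,
                                                   gain = 6,
                                                   baseline_rate = 10)),
                               seed = s + 20)
      act <- instantaneous_rate(sess$units[[1]], sess$duration)
      bootstrap_duration(act, beh, n_segments = 50, n_reps = 30,
                         seed = s)$sd
    }, 0)
    mean(sd_i)
  }, 0)
  ratio <- sds[1] / sds[2] # 4x the data, expect a shrink near sqrt(4) = 2
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3)
})

test_that("estimated duration increases monotonically with modulation sigma", {
  mean_dur <- sapply(c(0.05, 0.15, 0.4), function(sg) {
    mean(vapply(1:3, function(s) {
      beh <- generate_behavior(300, seed = s + 30)
      sess <- generate_session(beh, list(unit_spec(lag = -0.1,
                                                   modulation_sigma = sg,
                                                   gain = 4,
                                                   baseline_rate = 8)),
                               seed = s + 40)
      act <- instantaneous_rate(sess$units[[1]], sess$duration)
      modulation_metrics(compute_awd(act, beh))$duration
    }, 0))
  })
  expect_true(all(diff(mean_dur) > 0))
})

test_that("a blocked out-of-sample split gives honest, lower decode curves", {
  sess <- coupled_session(seed = 31, duration = 120, n_units = 6)
  enc <- fit_encoding(sess)
  bands <- default_bands()[2:4]
  sw_in <- two_point_decode_sweep(enc$denoised, sess$behavior, bands = bands)
  sw_cv <- two_point_decode_sweep(enc$denoised, sess$behavior, bands = bands,
                                  split = TRUE)
  expect_true(all(is.finite(sw_cv$performance)))
  expect_true(all(sw_cv$performance <= sw_in$performance + 0.05))
})
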