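test_that("the sigma to cutoff convention is f = 1/(2 pi sigma)", {
  expect_equal(gaussian_cutoff(0.14), 1.137, tolerance = 1e-3)
  bands <- default_bands()
  expect_length(bands, 7L)
  expect_equal(vapply(bands, function(b) b$center_freq, 0),
               1 / (2 * pi * c(0.014, 0.035, 0.071, 0.14, 0.35, 0.71, 1.4)),
               ignore_attr = TRUE)
  lp <- lowpass_band()
  expect_equal(lp$sigma_lowpass, 0.71)
  expect_equal(lp$sigma_highpass, 2.8)
})

test_that("a sinusoid at the cutoff keeps amplitude exp(-1/2) through the low-pass", {
  dt <- 0.01
  t <- seq(dt, 400, by = dt)
  sigma <- 0.14
  f_c <- 1 / (2 * pi * sigma)
  x <- sin(2 * pi * f_c * t)
  y <- gaussian_smooth(x, sigma, dt)
  # compare FFT amplitudes at the stimulus frequency, away from the edges
  core <- 2000:38000
  expect_equal(sd(y[core]) / sd(x[core]), exp(-0.5), tolerance = 0.005)
})

test_that("high-pass removes DC exactly and band-pass is linear", {
  dt <- 0.01
  x <- rep(5, 2000)
  expect_lt(max(abs(high_pass(x, 0.14, dt))), 1e-12)
  set.seed(1)
  a <- rnorm(3000); b <- rnorm(3000)
  band <- default_bands()[[4]]
  lhs <- band_pass(2 * a + 3 * b, band, dt)
  rhs <- 2 * band_pass(a, band, dt) + 3 * band_pass(b, band, dt)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("the envelope is invariant to a sign flip of the input", {
  set.seed(2)
  x <- rnorm(2000)
  band <- default_bands()[[3]]
  e1 <- envelope(band_pass(x, band))
  e2 <- envelope(band_pass(-x, band))
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("bands validate their stage ordering and sampling", {
  expect_error(band_spec(0.1, 0.2), "sigma_highpass")
  expect_error(band_pass(rnorm(100), band_spec(0.5, 0.004)), "sample")
})

test_that("band-velocity correlation finds the band and lag of the coupling", {
  beh <- generate_behavior(600, submovement_freq = 2.3, dwell_active = 8,
                           dwell_quiescent = 0.5, direction_tau = 0.15,
                           seed = 3)
  sp <- speed(beh)
  # broad-band activity leading the speed by 100 ms
  act <- c(sp[11:length(sp)], rep(sp[length(sp)], 10))
  bv <- band_velocity_correlation(act, beh)
  best <- which.max(bv$peak_r)
  expect_lt(abs(bv$peak_lag[best] - (-0.10)), 0.02)
})

test_that("independent activity stays within the circular-shift null band", {
  beh <- generate_behavior(300, seed = 4)
  set.seed(5)
  act <- rnorm(length(beh))
  bv <- band_velocity_correlation(act, beh)
  sp <- speed(beh)
  null_r <- vapply(1:20, function(i) {
    k <- sample(3000:(length(sp) - 3000), 1)
    max(abs(cor(c(sp[(k + 1):length(sp)], sp[1:k]), sp)))
  }, 0)
  expect_lt(max(bv$peak_r, na.rm = TRUE), max(quantile(null_r, 0.95), 0.1))
})

test_that("cross-frequency coupling recovers the phase of an AM test signal", {
  dt <- 0.01
  t <- seq(dt, 600, by = dt)
  slow <- sin(2 * pi * 0.1 * t)
  mk <- function(phase_shift)
    slow + 0.5 * (1 + 0.8 * sin(2 * pi * 0.1 * t + phase_shift)) *
      sin(2 * pi * 3 * t)
  prof0 <- cross_frequency_coupling(mk(0))
  expect_equal(nrow(prof0), 16L)
  expect_lt(abs(prof0$phase[which.max(prof0$amplitude)]), pi / 8)
  # the slow carrier sin(wt) has Hilbert phase wt - pi/2, so a gain term
  # 1 + 0.8 sin(wt + phi) peaks at slow phase -phi
  prof_shift <- cross_frequency_coupling(mk(-pi / 2))
  expect_lt(abs(prof_shift$phase[which.max(prof_shift$amplitude)] - pi / 2),
            pi / 8 + 1e-9)
})

test_that("cross-frequency coupling edge contracts hold", {
  expect_error(cross_frequency_coupling(rnorm(2000)), "cycles")
  flat <- cross_frequency_coupling(rep(1, 60000))
  expect_true(all(flat$amplitude[!is.na(flat$amplitude)] < 1e-9))
  # mean over phase bins matches the global mean fast amplitude
  set.seed(6)
  x <- rnorm(60000)
  prof <- cross_frequency_coupling(x)
  fast <- band_pass(x, band_spec_from_center(3))
  amp <- envelope(fast, smooth_sigma = 1 / (2 * pi * 1.5))
  expect_lt(abs(mean(prof$amplitude, na.rm = TRUE) - mean(amp)) / mean(amp),
            0.05)
})
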