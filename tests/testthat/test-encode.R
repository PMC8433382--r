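test_that("lagged kernel fits match the brute-force normal-equation oracle", {
  set.seed(1)
  n <- 600
  lags <- -20:19
  X <- cbind(rnorm(n), rnorm(n))
  w_true <- cbind(dnorm(lags, -5, 3), -dnorm(lags, 4, 2))
  y <- bruteforce_lagged_lsq(X, rnorm(n), lags)$prediction * 0 # layout only
  D_pred <- function(Xc, W) {
    out <- numeric(n)
    for (j in 1:2) for (li in seq_along(lags))
      out <- out + W[li, j] * Xc[((seq_len(n) - 1L - lags[li]) %% n) + 1L, j]
    out
  }
  y <- D_pred(X, w_true) + rnorm(n, sd = 0.1)
  fit <- fit_lagged_kernel(X, y, lags)
  oracle <- bruteforce_lagged_lsq(X, y, lags)
  expect_lt(max(abs(fit$weights - oracle$weights)), 1e-8)
  expect_lt(max(abs(fit$prediction - oracle$prediction)), 1e-8)
})

test_that("a noiseless linear model is recovered exactly", {
  set.seed(2)
  n <- 2000
  lags <- -30:29
  X <- cbind(rnorm(n), rnorm(n))
  w_true <- cbind(dnorm(lags, 0, 5), dnorm(lags, -8, 4))
  Xc <- sweep(X, 2, colMeans(X))
  y <- numeric(n)
  for (j in 1:2) for (li in seq_along(lags))
    y <- y + w_true[li, j] * Xc[((seq_len(n) - 1L - lags[li]) %% n) + 1L, j]
  fit <- fit_lagged_kernel(X, y, lags)
  expect_lt(sqrt(mean((fit$weights - w_true)^2)), 1e-6)
  expect_lt(fit$residual_sd, 1e-8)
})

test_that("the standard kernel grid spans -2..2 s with T = 400 taps", {
  beh <- generate_behavior(60, seed = 3)
  sess <- generate_session(beh, list(unit_spec(gain = 1)), seed = 4)
  enc <- fit_encoding(sess)
  expect_length(enc$lags, 400L)
  expect_equal(range(enc$lags) * 0.01, c(-2, 1.99))
  expect_equal(dim(enc$kernels[[1]]), c(400L, 2L))
})

test_that("encoding explains coupled units and degrades for out-of-support lags", {
  beh <- generate_behavior(300, dwell_active = 8, dwell_quiescent = 0.5,
                           direction_tau = 0.15, seed = 5)
  specs <- list(unit_spec(lag = -0.2, modulation_sigma = 0.02, gain = 2.5,
                          baseline_rate = 12, variable = "vx"),
                unit_spec(lag = -3.5, modulation_sigma = 0.02, gain = 2.5,
                          baseline_rate = 12, variable = "vx"))
  sess <- generate_session(beh, specs, seed = 6)
  enc <- fit_encoding(sess)
  expect_gt(enc$r2[1], enc$r2[2]) # -3.5 s lies outside the +-2 s support
})

test_that("rank-deficient designs are regularized and flagged", {
  set.seed(7)
  X <- cbind(rep(1, 500), rep(2, 500)) # constant velocity
  fit <- fit_lagged_kernel(X, rnorm(500), -5:4)
  expect_true(fit$flag_regularized)
  expect_true(all(is.finite(fit$weights)))
})

test_that("two-point decoding is invariant to unit permutation and fails on noise", {
  sess <- coupled_session(seed = 8, duration = 120, n_units = 6)
  enc <- fit_encoding(sess)
  sw1 <- two_point_decode_sweep(enc$denoised, sess$behavior)
  set.seed(9)
  sw2 <- two_point_decode_sweep(enc$denoised[sample(6), ], sess$behavior)
  expect_equal(sw1$performance, sw2$performance, tolerance = 1e-8)
  # pure-noise units carry no velocity information; the in-sample fit floor
  # scales with 1/sqrt(duration * bandwidth), so it is loosest for the
  # narrow slow bands and tight above 1 Hz
  sess240 <- coupled_session(seed = 11, duration = 240, n_units = 6)
  noise_act <- matrix(rnorm(6 * length(sess240$behavior)), 6)
  sw3 <- two_point_decode_sweep(noise_act, sess240$behavior)
  expect_lt(max(sw3$performance, na.rm = TRUE), 0.2)
  expect_lt(max(sw3$performance[sw3$center_freq >= 2], na.rm = TRUE), 0.1)
})

test_that("decoding the encoder prediction cannot beat the ground-truth coupling", {
  sess <- coupled_session(seed = 10, duration = 120, n_units = 6)
  truth <- do.call(rbind, lapply(sess$units, attr, "true_rate"))
  enc <- fit_encoding(sess)
  sw_truth <- two_point_decode_sweep(truth, sess$behavior)
  sw_fit <- two_point_decode_sweep(enc$denoised, sess$behavior)
  best_t <- max(sw_truth$performance, na.rm = TRUE)
  best_f <- max(sw_fit$performance, na.rm = TRUE)
  expect_lt(best_f, best_t + 0.05) # slack: in-sample kernels also fit noise
})
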