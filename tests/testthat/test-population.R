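test_that("preprocessing yields unit-norm, demeaned columns orthogonal to the global mode", {
  beh <- generate_behavior(120, seed = 1)
  specs <- lapply(1:5, function(i) unit_spec(lag = -0.1 * i, gain = 2,
                                             baseline_rate = 8))
  sess <- generate_session(beh, specs, seed = 2)
  # normalization contract before mode removal: every column has norm 1
  pop0 <- preprocess_population(sess, global_mode = FALSE)
  nrm0 <- sqrt(colSums(pop0$activity^2))
  expect_true(all(abs(nrm0 - 1) < 1e-9 | nrm0 < 1e-9))
  expect_lt(max(abs(colMeans(pop0$activity))), 1e-9)
  # after mode removal: columns orthogonal to p, norms can only shrink
  pop <- preprocess_population(sess)
  proj <- as.numeric(crossprod(pop$activity, pop$global_mode))
  expect_lt(max(abs(proj)), 1e-9)
  expect_equal(sqrt(sum(pop$global_mode^2)), 1, tolerance = 1e-12)
  expect_true(all(sqrt(colSums(pop$activity^2)) <= nrm0 + 1e-9))
})

test_that("global-mode removal never increases a column norm above 1", {
  beh <- generate_behavior(60, seed = 3)
  act <- generate_population_ar1(6, length(beh), 0.3, seed = 3)
  pop <- preprocess_population(act, behavior = beh)
  expect_true(all(sqrt(colSums(pop$activity^2)) <= 1 + 1e-9))
})

test_that("two-unit toy matrix reproduces hand-computed z-scores", {
  act <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE) # unit 1: 1,2; unit 2: 3,4
  pop <- preprocess_population(act, global_mode = FALSE)
  # z-scores per unit: (-.5,.5)/sd -> both rows (-1/sqrt(2), 1/sqrt(2)) * ...
  z <- (act - rowMeans(act)) / apply(act, 1, sd)
  z <- sweep(z, 2, colMeans(z))
  expect_equal(pop$activity, z, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("silent units are excluded with a message", {
  act <- rbind(generate_population_ar1(3, 1000, 0.3, seed = 4), 0)
  expect_message(pop <- preprocess_population(act, global_mode = FALSE),
                 "silent")
  expect_equal(nrow(pop$activity), 3L)
  expect_equal(pop$kept_units, 1:3)
})

test_that("constant speed yields no trials; trials span 1601 bins", {
  flat <- behavior_trace(rep(2, 3000), rep(0, 3000))
  tr <- detect_trials(flat)
  expect_length(tr$centers, 0L)
  expect_equal(tr$bins_per_trial, 1601L)
})

test_that("a single quiescence-to-movement step yields one trial at the step", {
  dt <- 0.01
  n <- 6000
  sp <- 1 + 2 / (1 + exp(-(seq_len(n) - 3000) / 30)) # smooth 1 -> 3 step at 30 s
  beh <- behavior_trace(sp, rep(0, n))
  tr <- detect_trials(beh)
  expect_length(tr$centers, 1L)
  expect_lt(abs(tr$centers - 30), 2)
})

test_that("trial centers too close to the session edge are dropped", {
  dt <- 0.01
  n <- 2400 # 24 s: a step at 21 s cannot host an 8 s window
  sp <- 1 + 2 / (1 + exp(-(seq_len(n) - 2100) / 30))
  beh <- behavior_trace(sp, rep(0, n))
  expect_length(detect_trials(beh)$centers, 0L)
})

test_that("trial correlation matrix contracts: ones, symmetry, noise floor", {
  set.seed(5)
  U <- 30
  v <- rnorm(U); v <- v / sqrt(sum(v^2))
  const_pop <- structure(list(activity = matrix(v, U, 4000), dt = 0.01,
                              global_mode = NULL, zero_cols = rep(FALSE, 4000)),
                         class = "population_matrix")
  trials <- structure(list(centers = 20, half_window = 8,
                           bins_per_trial = 1601L, dt = 0.01),
                      class = "trial_set")
  cm <- trial_correlation_matrix(const_pop, trials)
  expect_true(all(abs(cm - 1) < 1e-9))
  # white-noise population: off-diagonal near 0 within the 1/sqrt(U) scale
  act <- matrix(rnorm(U * 4000), U)
  pop <- preprocess_population(act, global_mode = FALSE)
  cm2 <- trial_correlation_matrix(pop, trials)
  expect_equal(cm2, t(cm2), tolerance = 1e-12)
  off <- cm2[abs(row(cm2) - col(cm2)) > 10]
  expect_lt(abs(mean(off)), 3 / sqrt(U) / sqrt(length(off) / 1601))
  expect_lt(sd(off), 3 / sqrt(U))
  expect_error(trial_correlation_matrix(pop, structure(
    list(centers = numeric(), half_window = 8, bins_per_trial = 1601L,
         dt = 0.01), class = "trial_set")), "no trials")
})

test_that("an exact exponential decay is fitted back to machine precision", {
  cc <- exp(-(0:399) * 0.01 / 0.3)
  fit <- fit_decay(cc, dt = 0.01)
  expect_equal(fit$tau, 0.3, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("decay fit flags all-nonpositive input and needs enough bins", {
  expect_warning(fit <- fit_decay(rep(-0.1, 100), dt = 0.01), "failed")
  expect_false(fit$converged)
  expect_error(fit_decay(exp(-(0:5) / 3), dt = 0.01), "distinct")
})

test_that("AR(1) population time constants are recovered within 15%", {
  for (tau in c(0.2, 0.8)) {
    act <- generate_population_ar1(40, 30000, tau, seed = round(100 * tau))
    pop <- preprocess_population(act, global_mode = FALSE)
    refs <- seq(500, 29500, by = 500)
    cc <- vapply(refs, function(r)
      as.numeric(crossprod(pop$activity[, r],
                           pop$activity[, r:(r + 300)])),
      numeric(301))
    fit <- fit_decay(rowMeans(cc), dt = 0.01)
    expect_lt(abs(fit$tau - tau) / tau, 0.15)
  }
})

test_that("the fitted time constant is invariant to unit relabeling", {
  act <- generate_population_ar1(20, 20000, 0.4, seed = 6)
  fit_for <- function(a) {
    pop <- preprocess_population(a, global_mode = FALSE)
    refs <- seq(500, 19000, by = 500)
    cc <- vapply(refs, function(r)
      as.numeric(crossprod(pop$activity[, r], pop$activity[, r:(r + 300)])),
      numeric(301))
    fit_decay(rowMeans(cc), dt = 0.01)$tau
  }
  set.seed(7)
  expect_equal(fit_for(act), fit_for(act[sample(20), ]), tolerance = 1e-9)
})

test_that("1/tau maps to the 16% attenuation point of a first-order low-pass", {
  expect_equal(lowpass_gain(1 / 0.5, 0.5), 1 / sqrt(1 + 4 * pi^2),
               tolerance = 1e-12)
  expect_equal(lowpass_gain(1 / 0.5, 0.5), 0.157, tolerance = 0.005)
})
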