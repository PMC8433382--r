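test_that("the snippet window is 76 samples with the trough at sample 16", {
  tpl <- lapply(synthetic_templates(), function(w) w * 160)
  raw <- generate_raw_trace(tpl[1], rates = 2, noise_sd = 0, duration = 20,
                            seed = 1)
  sn <- extract_snippets(raw, highpass = FALSE)
  expect_equal(ncol(sn$waveforms), 76L)
  expect_equal(sn$peak_sample, 16L)
  expect_true(all(apply(sn$waveforms, 1L, which.min) == 16L))
})

test_that("a flat trace yields no snippets and short traces are not errors", {
  raw <- raw_trace(rep(0, 30000))
  expect_equal(nrow(extract_snippets(raw, highpass = FALSE)$waveforms), 0L)
  tiny <- raw_trace(rep(0, 10))
  expect_equal(nrow(extract_snippets(tiny, highpass = FALSE)$waveforms), 0L)
})

test_that("a noiseless embedded template is recovered exactly", {
  tpl <- synthetic_templates()$narrow * 160
  raw <- generate_raw_trace(list(tpl), rates = 0.5, noise_sd = 0,
                            duration = 30, seed = 2)
  sn <- extract_snippets(raw, highpass = FALSE)
  expect_equal(nrow(sn$waveforms), nrow(raw$ground_truth))
  expect_equal(as.numeric(sn$waveforms[1, ]), tpl, tolerance = 1e-10)
  expect_equal(sn$peak_times, raw$ground_truth$peak_time, tolerance = 1e-6)
})

test_that("non-30 kHz traces recompute the window with a warning", {
  raw <- raw_trace(rnorm(20000), fs = 20000)
  expect_warning(sn <- extract_snippets(raw, highpass = FALSE), "window")
  expect_equal(ncol(sn$waveforms), round(0.0005 * 20000) + round(0.002 * 20000) + 1L)
})

test_that("identical snippets sort into exactly one unit containing all", {
  wf <- matrix(synthetic_templates()$narrow * 100, 40, 76, byrow = TRUE)
  sn <- spike_snippets(wf, seq_len(40), threshold = -40)
  units <- sort_snippets(sn, duration = 100, seed = 1)
  expect_length(units, 1L)
  expect_length(units[[1]]$spike_times, 40L)
})

test_that("sparse noise-like snippet sets hit the 0.1 Hz stop rule", {
  set.seed(3)
  wf <- matrix(rnorm(15 * 76, sd = 20), 15, 76)
  wf[, 16] <- wf[, 16] - 100 # negative troughs so the geometry is snippet-like
  sn <- spike_snippets(wf, sort(runif(15, 0, 300)), threshold = -80)
  units <- sort_snippets(sn, duration = 300, seed = 1)
  # 15 scattered events in 300 s: any stable cluster is below 0.1 Hz
  expect_length(units, 0L)
})

test_that("sorting is deterministic given the seed", {
  raw <- template_raw_trace(seed = 4, duration = 60)
  sn <- extract_snippets(raw)
  u1 <- sort_snippets(sn, duration = 60, seed = 9)
  u2 <- sort_snippets(sn, duration = 60, seed = 9)
  expect_identical(attr(u1, "assignment"), attr(u2, "assignment"))
})

test_that("member counts plus unassigned snippets account for every snippet", {
  raw <- template_raw_trace(seed = 5, duration = 60)
  sn <- extract_snippets(raw)
  units <- sort_snippets(sn, duration = 60, seed = 1)
  asg <- attr(units, "assignment")
  expect_length(asg, nrow(sn$waveforms))
  expect_equal(sum(asg > 0) + sum(asg == 0), nrow(sn$waveforms))
  for (k in seq_along(units))
    expect_equal(sum(asg == k), length(units[[k]]$spike_times))
})

test_that("a perfectly refractory train is always a single unit", {
  st <- seq(0.5, 99.5, by = 0.05) # 20 Hz, all ISIs 50 ms
  u <- classify_unit(sorted_unit(st, duration = 100))
  expect_equal(u$unit_class, "SU")
  # a train with heavy sub-2 ms ISI contamination is a multiunit
  set.seed(6)
  base <- sort(runif(2000, 0, 100))
  contaminated <- sort(c(base, base + 0.001))
  u2 <- classify_unit(sorted_unit(contaminated, duration = 100))
  expect_equal(u2$unit_class, "MU")
})

test_that("mu_rate is zero when lags without spike pairs exist", {
  # sparse periodic trains: unit_b fires only 100 ms after unit_a
  ta <- seq(1, 99, by = 1)
  ua <- sorted_unit(ta, duration = 100)
  ub <- sorted_unit(ta + 0.1, duration = 100)
  expect_equal(mu_rate(ua, ub, 100), 0)
  expect_error(mu_rate(ua, ua, 100), "itself")
})
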