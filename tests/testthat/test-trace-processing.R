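test_that("delta-F/F0 zeroes the baseline window and handles edge cases", {
  p <- bee_protocol()
  # constant trace -> all zeros
  d0 <- delta_f_over_f0(fluorescence_trace(rep(100, 100), p))
  expect_equal(d0$values, rep(0, 100))
  expect_equal(d0$baseline_value, 100)

  # baseline 100, response 110 -> 0.10 in the response window
  v <- rep(100, 100); v[17:25] <- 110
  d <- delta_f_over_f0(fluorescence_trace(v, p))
  expect_equal(d$values[17:19], rep(0.10, 3))
  expect_equal(mean(d$values[10:14]), 0)

  expect_error(delta_f_over_f0(fluorescence_trace(rep(0.0001, 100), p) |>
                                 (\(tr) { tr$values <- tr$values - 1; tr })()),
               "non-physical baseline")
})

test_that("delta traces are invariant under global gain", {
  p <- bee_protocol()
  set.seed(21)
  v <- 100 + cumsum(rnorm(100))
  v <- pmax(v, 1)
  d1 <- delta_f_over_f0(fluorescence_trace(v, p))
  d2 <- delta_f_over_f0(fluorescence_trace(7.3 * v, p))
  expect_equal(d1$values, d2$values, tolerance = 1e-12)
})

test_that("blank subtraction is framewise and exact", {
  p <- bee_protocol()
  set.seed(22)
  base <- rep(0, 100) + 0.02 * sin(seq_len(100) / 9)
  blank <- new_delta_trace_for_test(base, p)
  expect_equal(blank_subtraction(blank, blank)$values, rep(0, 100))

  boxcar <- rep(0, 100); boxcar[17:19] <- 0.05
  sig <- new_delta_trace_for_test(base + boxcar, p)
  expect_equal(blank_subtraction(sig, blank)$values, boxcar)

  short <- new_delta_trace_for_test(base[1:50], acq_protocol("bee", n_frames = 50))
  expect_error(blank_subtraction(sig, short), "length")
})

test_that("ratio series follows the Fura-2 arithmetic", {
  p <- bee_protocol()
  f380 <- rep(200, 100)
  # F340 = 2 F380 -> R = 2 everywhere, delta-R/R = 0
  r <- ratio_timeseries(fluorescence_trace(2 * f380, p),
                        fluorescence_trace(f380, p))
  expect_equal(r$values, rep(2, 100))
  expect_equal(delta_r_over_r(r)$values, rep(0, 100))

  # +5% / -5% at the stimulus -> (1.05/0.95) - 1 ~ +10.53%
  f340 <- rep(400, 100); f340[17:19] <- 400 * 1.05
  f380b <- f380; f380b[17:19] <- 200 * 0.95
  d <- delta_r_over_r(ratio_timeseries(fluorescence_trace(f340, p),
                                       fluorescence_trace(f380b, p)))
  expect_equal(d$values[17:19], rep(1.05 / 0.95 - 1, 3), tolerance = 1e-12)

  # non-positive F380 outside the baseline is masked with a warning
  f380c <- f380; f380c[60] <- 0
  expect_warning(ratio_timeseries(fluorescence_trace(f340, p),
                                  fluorescence_trace(f380c, p)),
                 "masked")
  f380d <- f380; f380d[12] <- -1
  expect_error(ratio_timeseries(fluorescence_trace(f340, p),
                                fluorescence_trace(f380d, p)),
               "baseline window")
})

test_that("median filter matches the brute-force per-axis oracle exactly", {
  expect_equal(median_filter_3(rep(4, 10)), rep(4, 10))
  expect_equal(median_filter_3(c(1, 5, 1))[2], 1)

  set.seed(23)
  for (rep_i in 1:3) {
    a <- array(rnorm(10 * 10 * 10), c(10, 10, 10))
    expect_identical(median_filter_3(a), brute_median_filter_3(a))
  }
})

test_that("median filter never widens the value range and fixes constants", {
  set.seed(24)
  a <- array(runif(8 * 8 * 8), c(8, 8, 8))
  f <- median_filter_3(a)
  expect_gte(min(f), min(a))
  expect_lte(max(f), max(a))
  # idempotent on monotone vectors (width-3 median of monotone data is identity)
  v <- sort(rnorm(30))
  expect_equal(median_filter_3(v), v)
})

test_that("log bleach correction removes a pure log decay to round-off", {
  t <- seq_len(100)
  trace <- 0.2 - 0.04 * log(t)
  out <- log_bleach_correction(trace, exclusion = c(15, 40))
  expect_lt(sqrt(mean(out^2)), 1e-8)

  # decay + boxcar transient inside the exclusion window: boxcar recovered
  boxcar <- rep(0, 100); boxcar[17:19] <- 0.05
  out2 <- log_bleach_correction(trace + boxcar, exclusion = c(15, 40))
  expect_equal(out2[17:19], boxcar[17:19], tolerance = 0.02 * 0.05)

  expect_warning(out3 <- log_bleach_correction(rep(0.5, 100), exclusion = c(15, 40)),
                 "constant input")
  expect_equal(out3, rep(0, 100), tolerance = 1e-12)
})

test_that("response amplitude uses the convention windows and ignores offsets", {
  p <- bee_protocol()
  z <- new_delta_trace_for_test(rep(0, 100), p)
  expect_equal(response_amplitude(z, "bee"), 0)

  v <- rep(0, 100); v[17:19] <- 1
  d <- new_delta_trace_for_test(v, p)
  expect_equal(response_amplitude(d, "bee"), 1)
  # additive constant cancels in the bee convention
  d_off <- new_delta_trace_for_test(v + 0.37, p)
  expect_equal(response_amplitude(d_off, "bee"), 1, tolerance = 1e-12)

  pf <- acq_protocol("fly")
  vf <- rep(0, 100); vf[17:31] <- 0.2
  expect_equal(response_amplitude(new_delta_trace_for_test(vf, pf), "fly"), 0.2)
  expect_error(response_amplitude(d, "mosquito"), "unknown amplitude convention")
})

test_that("noiseless pipelines recover planted amplitudes end to end", {
  # fly: log bleach + blank-trial subtraction
  cfg_fly <- sim_config(preset = "fly", bleach = list(model = "log", a = 1, b = -0.01))
  for (amp in c(0.005, 0.02, 0.05)) {
    sig <- simulate_trace(cfg_fly, amp)
    blank <- simulate_trace(cfg_fly, 0)
    d <- blank_subtraction(delta_f_over_f0(sig$trace),
                           delta_f_over_f0(blank$trace))
    expect_lt(abs(response_amplitude(d, "fly") - amp) / amp, 0.02)
  }
  # bee: ratiometric + median filter + log bleach correction
  cfg_bee <- sim_config(preset = "bee", bleach = list(model = "log", a = 1, b = -0.01))
  rois <- roi_set(list(glom = cbind(x = c(3, 12, 12, 3), y = c(3, 3, 12, 12))))
  for (amp in c(0.01, 0.05)) {
    sim <- simulate_ratiometric_stack(cfg_bee, rois, c(glom = amp))
    t340 <- extract_roi_traces(sim$f340, rois)[, 1]
    t380 <- extract_roi_traces(sim$f380, rois)[, 1]
    d <- delta_r_over_r(t340 / t380, cfg_bee$protocol)
    d <- log_bleach_correction(median_filter_3(d))
    expect_lt(abs(response_amplitude(d, "bee") - amp) / amp, 0.02)
  }
})
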