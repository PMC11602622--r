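test_that("generators are bit-identical for identical config and seed", {
  cfg <- sim_config(noise_sd = 2, seed = 99L)
  a <- simulate_trace(cfg, 0.03)
  b <- simulate_trace(cfg, 0.03)
  expect_identical(a$trace$values, b$trace$values)

  # substreams: replicate 1 unchanged when more replicates are drawn later
  r1 <- simulate_trace(cfg, 0.03, replicate = 1)
  r2 <- simulate_trace(cfg, 0.03, replicate = 2)
  expect_false(identical(r1$trace$values, r2$trace$values))
  expect_identical(r1$trace$values, simulate_trace(cfg, 0.03, replicate = 1)$trace$values)

  pan1 <- simulate_response_panel(matrix(1, 2, 3), noise_sd = 0.5, seed = 5)
  pan2 <- simulate_response_panel(matrix(1, 2, 3), noise_sd = 0.5, seed = 5)
  expect_identical(pan1$responses$amplitude, pan2$responses$amplitude)
})

test_that("noiseless bleach-free traces are exact identities", {
  cfg <- sim_config(preset = "bee")
  flat <- simulate_trace(cfg, 0)
  expect_equal(flat$trace$values, rep(cfg$baseline, cfg$n_frames))

  st <- simulate_trace(cfg, 0.10)
  amp <- response_amplitude(delta_f_over_f0(st$trace), "bee")
  expect_equal(amp, 0.10, tolerance = 1e-12)
  expect_error(simulate_trace(cfg, -1.5), "-1")
})

test_that("noisy amplitude estimates are unbiased within Monte-Carlo error", {
  cfg <- sim_config(preset = "bee", noise_sd = 1, seed = 7L)
  amps <- vapply(1:50, function(r) {
    st <- simulate_trace(cfg, 0.05, replicate = r)
    response_amplitude(delta_f_over_f0(st$trace), "bee")
  }, numeric(1))
  sem <- sd(amps) / sqrt(length(amps))
  expect_lt(abs(mean(amps) - 0.05), 2 * sem)
})

test_that("ratiometric stacks plant exact delta-R/R amplitudes", {
  cfg <- sim_config(preset = "bee")
  rois <- roi_set(list(a = cbind(x = c(2, 8, 8, 2), y = c(2, 2, 8, 8)),
                       b = cbind(x = c(12, 20, 20, 12), y = c(12, 12, 20, 20))))
  # zero amplitudes everywhere -> ratio pipeline returns 0 for every ROI
  sim0 <- simulate_ratiometric_stack(cfg, rois, c(a = 0, b = 0))
  for (nm in c("a", "b")) {
    r <- extract_roi_traces(sim0$f340, rois)[, nm] /
      extract_roi_traces(sim0$f380, rois)[, nm]
    expect_equal(response_amplitude(delta_r_over_r(r, cfg$protocol), "bee"), 0)
  }

  # one ROI planted at 1%: only that ROI exceeds 0.5% after processing
  sim1 <- simulate_ratiometric_stack(cfg, rois, c(a = 0.01, b = 0))
  amps <- vapply(c("a", "b"), function(nm) {
    r <- extract_roi_traces(sim1$f340, rois)[, nm] /
      extract_roi_traces(sim1$f380, rois)[, nm]
    response_amplitude(delta_r_over_r(r, cfg$protocol), "bee")
  }, numeric(1))
  expect_gt(amps["a"], 0.005)
  expect_lt(abs(amps["b"]), 1e-9)

  # channel swap inverts the recovered sign
  rsw <- extract_roi_traces(sim1$f380, rois)[, "a"] /
    extract_roi_traces(sim1$f340, rois)[, "a"]
  asw <- response_amplitude(delta_r_over_r(rsw, cfg$protocol), "bee")
  expect_lt(asw, 0)

  # overlapping ROIs rejected
  bad <- roi_set(list(a = cbind(x = c(2, 8, 8, 2), y = c(2, 2, 8, 8)),
                      b = cbind(x = c(5, 12, 12, 5), y = c(5, 5, 12, 12))))
  expect_error(simulate_ratiometric_stack(cfg, bad, c(a = 0, b = 0)),
               "overlapping")
})

test_that("response panels reproduce planted spectra and solvent null", {
  sp <- rbind(R1 = c(5, 1, 0), R2 = c(0, 2, 4))
  colnames(sp) <- c("odorA", "odorB", "odorC")
  pan <- simulate_response_panel(sp, noise_sd = 0, n_animals = 4)
  means <- response_spectra(pan$responses)
  expect_equal(means[, c("odorA", "odorB", "odorC")], sp)
  expect_equal(unname(means[, "solvent"]), c(0, 0))

  # specialist spectrum forces sparseness 1
  spec <- simulate_response_panel(rbind(spec = c(3, 0, 0, 0)), noise_sd = 0,
                                  n_animals = 3, add_solvent = FALSE)
  s <- sparseness(response_spectra(spec$responses)["spec", ])
  expect_equal(s$S, 1, tolerance = 1e-12)

  expect_error(simulate_response_panel(sp, n_animals = 1), "n_animals")
  expect_error(simulate_response_panel(-sp), "nonnegative")
})

test_that("dose series honor the Hill ground truth and reject bad input", {
  s <- simulate_dose_series(ec50 = 100, hill = 2, top = 1, bottom = 0.1,
                            noise_sd = 0, n_animals = 2)
  one <- s$series[s$series$animal == "a1", ]
  expect_equal(one$amplitude[one$dose == 0], 0.1)
  expect_equal(one$amplitude[one$dose == 100], (0.1 + 1) / 2)
  expect_error(simulate_dose_series(hill = 0), "Hill")
  expect_error(simulate_dose_series(doses = c(0, 1, 10)), "positive")
})

test_that("spike trains have the planted rate structure", {
  # stim rate == baseline rate: mean response ~ 0 over replicates
  diffs <- vapply(1:40, function(i) {
    tr <- simulate_spike_train(20, 20, c(3, 4), 20, seed = i)$train
    mean_response_rate(tr, c(3, 4), c(0, 3))
  }, numeric(1))
  sem <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 2 * sem + 1e-9)

  reg <- simulate_spike_train(100, 100, c(0.5, 1.5), 2, regular = TRUE)$train
  expect_equal(instantaneous_frequency(reg, seq(0.2, 1.8, by = 0.05)),
               rep(100, 33), tolerance = 1e-9)

  expect_error(simulate_spike_train(10, 10, c(1, 2), duration = 0), "duration")
  expect_error(simulate_spike_train(-1, 10, c(1, 2), 5), "rates")
})
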