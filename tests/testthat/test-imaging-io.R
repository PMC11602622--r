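test_that("protocol presets carry the standard quantification windows", {
  bee <- acq_protocol("bee")
  expect_equal(bee$baseline_window, c(10L, 14L))
  expect_equal(bee$stimulus_window, c(15L, 20L))
  expect_equal(bee$response_window, c(17L, 19L))
  expect_equal(bee$prestim_window, c(9L, 11L))
  expect_equal(bee$bleach_exclusion, c(15L, 40L))  # onset + 5 s at 5 Hz
  expect_equal(bee$frame_rate, 5)

  fly <- acq_protocol("fly")
  expect_equal(fly$baseline_window, c(10L, 14L))
  expect_equal(fly$response_window, c(17L, 31L))
  expect_equal(fly$prestim_window, fly$baseline_window)
})

test_that("protocol validation rejects impossible window layouts", {
  expect_error(acq_protocol("bee", baseline_window = c(14, 16)),
               "baseline_window must end before")
  expect_error(acq_protocol("bee", n_frames = 18), "exceeds")
  expect_error(acq_protocol("custom"), "response_window")
})

test_that("protocol YAML round-trips and rejects unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_protocol(acq_protocol("bee"), path)
  p2 <- read_protocol(path)
  expect_equal(p2$response_window, c(17L, 19L))
  expect_equal(p2$bleach_exclusion, c(15L, 40L))

  writeLines(c("preset: bee", "stim_duration: 5"), path)
  expect_error(read_protocol(path), "unknown protocol keys: stim_duration")

  writeLines(c("preset: bee", "  broken: [unclosed"), path)
  expect_error(read_protocol(path), "malformed protocol YAML")
})

test_that("TIFF stacks round-trip losslessly for 12-bit integer data", {
  set.seed(11)
  a <- array(sample(0:4095, 5 * 8 * 6, replace = TRUE), c(5, 8, 6))
  st <- frame_stack(a, frame_rate = 5, wavelength = "340")
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  st2 <- read_stack(path, frame_rate = 5, wavelength = "340")
  expect_equal(unclass(st2)[seq_along(a)], as.numeric(a))
  expect_identical(attr(st2, "wavelength"), "340")
})

test_that("unreadable or truncated stack files raise a format error", {
  path <- withr::local_tempfile(fileext = ".tif")
  set.seed(12)
  a <- array(sample(0:4095, 20 * 16 * 16, replace = TRUE), c(20, 16, 16))
  write_stack(frame_stack(a), path)
  bytes <- readBin(path, "raw", file.size(path))
  writeBin(bytes[seq_len(200)], path)  # chop the file mid-way
  expect_error(read_stack(path), "TIFF")
  expect_error(read_stack(withr::local_tempfile(fileext = ".tif")), "not found")
})

test_that("frame_stack validates its invariants", {
  expect_error(frame_stack(array(-1, c(2, 2, 2))), ">= 0")
  expect_error(frame_stack(matrix(1, 2, 2)), "frames x height x width")
  expect_error(frame_stack(array(1, c(0, 2, 2))), "at least one frame")
})

test_that("ROI JSON round-trips and masks respect image bounds", {
  rois <- roi_set(list(left = cbind(x = c(1, 6, 6, 1), y = c(1, 1, 6, 6)),
                       right = cbind(x = c(10, 14, 14, 10), y = c(2, 2, 8, 8))))
  path <- withr::local_tempfile(fileext = ".json")
  write_rois(rois, path)
  rois2 <- read_rois(path)
  expect_equal(rois2$polygons, rois$polygons)

  masks <- roi_masks(rois, c(16, 16))
  expect_true(all(vapply(masks, sum, 1) > 0))
  # a polygon fully outside the image has no pixel
  out <- roi_set(list(gone = cbind(x = c(30, 40, 40), y = c(30, 30, 40))))
  expect_error(roi_masks(out, c(16, 16)), "covers no pixel")
})

test_that("trace extraction is the unweighted ROI mean and is linear", {
  a <- array(7, c(10, 12, 12))
  st <- frame_stack(a)
  rois <- roi_set(list(r = cbind(x = c(2, 6, 6, 2), y = c(2, 2, 6, 6))))
  tr <- extract_roi_traces(st, rois)
  expect_equal(dim(tr), c(10L, 1L))
  expect_equal(unname(tr[, 1]), rep(7, 10))

  # one bright pixel inside a 4-pixel ROI: trace = (3 bg + bright) / 4
  b <- array(10, c(3, 6, 6))
  b[, 3, 3] <- 110
  rois4 <- roi_set(list(q = cbind(x = c(1.5, 3.5, 3.5, 1.5),
                                  y = c(1.5, 1.5, 3.5, 3.5))))
  m <- roi_masks(rois4, c(6, 6))
  expect_equal(sum(m$q), 4L)
  tr4 <- extract_roi_traces(frame_stack(b), rois4)
  expect_equal(unname(tr4[, 1]), rep((3 * 10 + 110) / 4, 3))

  # linearity: extract(a*S + b) = a*extract(S) + b
  set.seed(13)
  s1 <- array(runif(10 * 12 * 12, 1, 10), c(10, 12, 12))
  t1 <- extract_roi_traces(frame_stack(s1), rois)
  t2 <- extract_roi_traces(frame_stack(3 * s1 + 2), rois)
  expect_equal(t2, 3 * t1 + 2, tolerance = 1e-12)
})

test_that("CSV tables round-trip and enforce required columns", {
  df <- data.frame(animal = "a1", receptor = "AmelOR11",
                   stimulus = c("9-ODA", "solvent"), amplitude = c(1.2, 0.1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(df, path)
  back <- read_table_csv(path, required = c("animal", "stimulus", "amplitude"))
  expect_equal(back$amplitude, df$amplitude)
  expect_error(read_table_csv(path, required = "dose"), "dose")
})
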