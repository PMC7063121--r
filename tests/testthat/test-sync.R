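pulse_runs <- function(x, fs) {
  r <- rle(x > 0.5)
  widths <- r$lengths[r$values] / fs
  widths
}

test_that("frame for minute 0 is 16 narrow pulses", {
  x <- encode_reference_signal(1, 1000)
  w <- pulse_runs(x, 1000)
  expect_length(w, 16)
  expect_true(all(abs(w - 0.04) < 2e-3))
})

test_that("frame for minute 5 has wide pulses in slots 0 and 2", {
  x <- encode_reference_signal(6, 500)
  # frame of minute 5 starts at 300 s
  frame <- x[(300 * 500 + 1):(304 * 500)]
  w <- pulse_runs(frame, 500)
  expect_length(w, 16)
  wide <- w > 0.08
  expect_equal(which(wide), c(1L, 3L))
})

test_that("encoding capacity is 16 bits", {
  expect_error(encode_reference_signal(70000, 100), "16-bit")
})

test_that("decode inverts encode and is shift-equivariant", {
  fs <- 250
  x <- encode_reference_signal(11, fs)
  mk <- decode_reference_signal(x, fs)
  expect_equal(mk$minute, 0:10)
  expect_equal(mk$device_time, 60 * (0:10), tolerance = 1e-6)
  # delay by 3.2 s: same minutes, device_times shifted
  delayed <- c(numeric(round(3.2 * fs)), x)
  mk2 <- decode_reference_signal(delayed, fs)
  expect_equal(mk2$minute, mk$minute)
  expect_equal(mk2$device_time, mk$device_time + 3.2, tolerance = 1e-6)
})

test_that("a zeroed frame is skipped, the others decode intact", {
  fs <- 250
  x <- encode_reference_signal(6, fs)
  x[(120 * fs + 1):(124 * fs)] <- 0   # erase the minute-2 frame
  mk <- decode_reference_signal(x, fs)
  expect_equal(mk$minute, c(0, 1, 3, 4, 5))
  expect_error(decode_reference_signal(numeric(1000), fs),
               "no decodable sync frame")
})

test_that("device clock offsets are recovered by alignment", {
  cfg <- sim_config(
    participant_count = 1, between_subject_cv = 0, sync = TRUE,
    device_clock_offsets = list(ppg = 1.5, nirs = -2.3, tilt = 0.8),
    rng_seed = 21)
  s <- simulate_session(cfg, 1, "sit_to_stand", 1)
  expect_false(s$pre_aligned)
  al <- align_session(s)
  fits <- al$alignment
  expect_equal(fits$offset[fits$device == "ppg"], 1.5, tolerance = 0.02)
  expect_equal(fits$offset[fits$device == "nirs"], -2.3, tolerance = 0.03)
  # after alignment all channels' clocks agree: onset detected from tilt
  # matches the configured onset
  p <- prepare_repeat(al)
  expect_equal(p$onset, cfg$baseline_s, tolerance = 1.5)
})

test_that("10-ppm clock drift leaves residual misalignment below one
           25-Hz sample", {
  cfg <- sim_config(
    participant_count = 1, between_subject_cv = 0, sync = TRUE,
    device_clock_offsets = list(nirs = 4),
    device_clock_drift_ppm = list(nirs = 10),
    baseline_s = 90, post_s = 180, rng_seed = 22)
  s <- simulate_session(cfg, 1, "sit_to_stand", 1)
  al <- align_session(s)
  f <- al$alignment[al$alignment$device == "nirs", ]
  # reconstruct marker positions: residual error at both ends of the record
  t_end <- 240
  err0 <- abs((0 * (1 + 1e-5) + 4 - f$offset) / f$slope - 0)
  err1 <- abs((t_end * (1 + 1e-5) + 4 - f$offset) / f$slope - t_end)
  expect_lt(err0, 1 / 25)
  expect_lt(err1, 1 / 25)
})

test_that("alignment without sync or pre-alignment declaration errors", {
  s <- clean_session()
  s$pre_aligned <- FALSE
  expect_error(align_session(s), "sync")
})
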