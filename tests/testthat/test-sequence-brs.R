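test_that("ramp detection finds maximal monotone runs", {
  r <- detect_ramps(c(120, 121.5, 123, 124.5))
  expect_equal(nrow(r), 1)
  expect_equal(r$length, 4)
  expect_equal(r$direction, "up")
  expect_equal(nrow(detect_ramps(rep(120, 10))), 0)
  # down-ramp
  rd <- detect_ramps(c(130, 128, 126, 125, 130))
  expect_equal(rd$direction, "down")
  expect_equal(rd$start, 1)
  expect_equal(rd$end, 4)
})

test_that("ramp detection matches the brute-force scanner on random
           series", {
  set.seed(6)
  for (i in 1:100) {
    sbp <- 125 + cumsum(rnorm(50, 0, 1.5))
    got <- detect_ramps(sbp)
    want <- brute_force_ramps(sbp)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      w <- do.call(rbind, want)
      expect_equal(got$start, w[, 1])
      expect_equal(got$end, w[, 2])
    }
  }
})

test_that("constructed ramp yields the exact sequence slope and BEI", {
  beats <- tibble::tibble(sbp = c(120, 121.5, 123, 124.5),
                          ibi_ms = c(800, 808, 816, 824))
  res <- sequence_brs(beats, lag = 0)
  expect_equal(res$n_ramps, 1)
  expect_equal(res$n_sequences, 1)
  expect_equal(res$brs, 16 / 3, tolerance = 1e-12)
  expect_equal(res$sequences$r, 1, tolerance = 1e-12)
  expect_equal(res$bei, 1)
})

test_that("anti-concordant IBI segments are rejected", {
  beats <- tibble::tibble(sbp = c(120, 121.5, 123, 124.5),
                          ibi_ms = c(824, 816, 808, 800))
  res <- sequence_brs(beats, lag = 0)
  expect_equal(res$n_ramps, 1)
  expect_equal(res$n_sequences, 0)
  expect_true(is.na(res$brs))
  expect_equal(res$bei, 0)
})

test_that("raising thresholds never increases sequence counts or BEI", {
  set.seed(9)
  b <- simulate_resting_beats(duration_s = 300, gain = 8, lag = 1,
                              sbp_noise_sd = 1, ibi_noise_sd = 4, seed = 12)
  base <- sequence_brs(b, lag = 1)
  stricter_sbp <- sequence_brs(b, lag = 1, sbp_threshold = 2)
  stricter_r <- sequence_brs(b, lag = 1, r_min = 0.95)
  expect_lte(stricter_sbp$n_sequences, base$n_sequences)
  expect_lte(stricter_r$n_sequences, base$n_sequences)
  expect_true(is.na(base$bei) || (base$bei >= 0 && base$bei <= 1))
})

test_that("sequence BRS recovers the simulated resting gain", {
  for (g in c(5, 8, 12)) {
    b <- simulate_resting_beats(duration_s = 300, gain = g, lag = 1,
                                seed = 31)
    res <- sequence_brs(b, lag = 1)
    expect_gt(res$n_sequences, 0)
    expect_equal(res$brs, g, tolerance = 0.02)
  }
})

test_that("BEI is the qualifying-ramp fraction", {
  expect_equal(bei(4, 3), 0.75)
  expect_equal(bei(5, 5), 1)
  expect_equal(bei(5, 0), 0)
  expect_true(is.na(bei(0, 0)))
})
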