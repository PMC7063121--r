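test_that("band-pass removes DC and passes the cardiac band", {
  fs <- 1000
  n <- 120 * fs
  t <- (0:(n - 1)) / fs
  mid <- (30 * fs):(90 * fs)
  # constant -> ~0 (stop-band at DC)
  y0 <- bandpass_ppg(rep(3, n), fs)
  expect_lt(max(abs(y0[mid])), 1e-4)
  # 1 Hz preserved within 5%
  y1 <- bandpass_ppg(sin(2 * pi * 1 * t), fs)
  expect_equal(sd(y1[mid]) / sd(sin(2 * pi * 1 * t[mid])), 1,
               tolerance = 0.05)
  # 0.01 Hz attenuated by >= 20 dB
  y2 <- bandpass_ppg(sin(2 * pi * 0.01 * t), fs)
  expect_lt(sd(y2[mid]) / sd(sin(2 * pi * 0.01 * t)[mid]), 0.1)
  expect_error(bandpass_ppg(rep(1, 100), fs = 15), "too low")
})

test_that("waveform resampling is accurate and exact on constants", {
  r <- resample_25(rep(5, 4000), fs = 1000)
  expect_equal(r$value, rep(5, length(r$value)), tolerance = 1e-9)
  # 1 Hz sinusoid: RMS error < 1% vs the analytic signal (interior)
  fs <- 1000
  t <- (0:(120 * fs - 1)) / fs
  r1 <- resample_25(sin(2 * pi * t), fs)
  interior <- r1$t > 5 & r1$t < 115
  err <- r1$value[interior] - sin(2 * pi * r1$t[interior])
  expect_lt(sqrt(mean(err^2)), 0.01)
  # 50 Hz native (NIRS)
  t5 <- (0:(120 * 50 - 1)) / 50
  r2 <- resample_25(sin(2 * pi * t5), 50)
  i2 <- r2$t > 5 & r2$t < 115
  expect_lt(sqrt(mean((r2$value[i2] - sin(2 * pi * r2$t[i2]))^2)), 0.01)
  expect_error(resample_25(numeric(0), 100), "empty")
})

test_that("beat series hold onto the 25-Hz grid keeps previous values", {
  grid <- seq(0, 1.2, by = 0.04)
  h <- hold_25(c(0, 0.8), c(800, 820), grid)
  expect_equal(h$value[grid < 0.8], rep(800, sum(grid < 0.8)))
  expect_equal(h$value[grid >= 0.8], rep(820, sum(grid >= 0.8)))
})

test_that("standardization zeroes the baseline and the moving average is
           linear-phase", {
  t <- seq(0, 120, by = 0.04)
  set.seed(1)
  x <- rnorm(length(t))
  p <- standardize_and_smooth(t, x, onset = 60)
  bl <- p$t >= 0 & p$t < 60
  expect_equal(mean(p$std[bl]), 0, tolerance = 1e-12)
  expect_equal(sd(p$std[bl]), 1, tolerance = 1e-12)
  # 5-s MA of a linear ramp reproduces the ramp in the interior
  ramp <- 2 * t + 1
  pr <- standardize_and_smooth(t, ramp, onset = 60)
  interior <- p$t > 3 & p$t < 117
  expect_equal(pr$smooth_raw[interior], ramp[interior], tolerance = 1e-9)
  # degenerate baseline
  expect_error(standardize_and_smooth(t, rep(1, length(t)), onset = 60),
               "degenerate")
})

test_that("onset detection finds a held threshold crossing", {
  t <- seq(0, 400, by = 0.02)
  ang <- 90 / (1 + exp(-(t - 301) * 4))   # fast sigmoid, 5 deg at ~300.3
  onset <- detect_onset(t, ang)
  expect_lt(abs(onset - 300.3), 0.2)
  expect_error(detect_onset(t, rep(0, length(t))), "no movement onset")
  # a 3-degree step never crosses the 5-degree threshold
  step3 <- ifelse(t > 300, 3, 0)
  expect_error(detect_onset(t, step3), "no movement onset")
})

test_that("quality gate applies the 10/10/20-s heartbeat-gap rules", {
  onset <- 300
  beats_with_gap <- function(gap_start, gap_len) {
    t <- seq(200, 480, by = 0.8)
    t[t < gap_start | t > gap_start + gap_len]
  }
  # clean repeat: no discards
  q0 <- assess_quality(list(ppg = seq(200, 480, by = 0.8)), onset)
  expect_false(any(q0$discard))
  # 12-s dropout in baseline -> discard with a reason naming the window
  q1 <- assess_quality(list(ppg = beats_with_gap(270, 12)), onset)
  expect_true(q1$discard)
  expect_match(q1$reason, "baseline")
  expect_gt(q1$gap_baseline, 10)
  # 15-s dropout in minute 3 -> retained (15 <= 20)
  q2 <- assess_quality(list(ppg = beats_with_gap(430, 15)), onset)
  expect_false(q2$discard)
  # 25-s dropout in minute 2 -> discard
  q3 <- assess_quality(list(ppg = beats_with_gap(370, 25)), onset)
  expect_true(q3$discard)
  # 11-s dropout in minute 1 -> discard
  q4 <- assess_quality(list(ppg = beats_with_gap(310, 11)), onset)
  expect_true(q4$discard)
  # missing-sample channel judged with the same thresholds
  t50 <- seq(200, 480, by = 0.02)
  na <- t50 > 250 & t50 < 262
  q5 <- assess_quality(list(), onset,
                       sampled = list(o2hb = list(t = t50, na = na)))
  expect_true(q5$discard)
})
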