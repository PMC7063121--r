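test_that("R-peak detection matches simulated beat times within 1 ms", {
  s <- clean_session()
  ecg <- get_channel(s, "ecg")
  r <- detect_r_peaks(ecg$x, ecg$fs)
  tr <- s$truth$beats$t
  expect_equal(length(r), length(tr))
  expect_lt(max(abs(r - tr)), 1e-3)
  expect_error(detect_r_peaks(numeric(0), 1000), "empty")
  expect_error(detect_r_peaks(rep(0, 10000), 1000), "no R-peaks")
  # event-series input is passed through unchanged
  expect_equal(detect_r_peaks(c(3, 1, 2), fs = NULL), c(1, 2, 3))
})

test_that("upstroke detection is near-complete and accurate on clean PPG", {
  s <- clean_session()
  fp <- get_channel(s, "finger_ppg")
  ppg <- bandpass_ppg(fp$x, fp$fs)
  r <- s$truth$beats$t
  hisens <- detect_ppg_upstrokes(ppg, fp$fs, r, 1.5)
  expect_gte(mean(hisens$detected), 0.99)
  err <- hisens$upstroke_time - (r + s$truth$beats$ptt)
  expect_lt(max(abs(err), na.rm = TRUE), 2 / fp$fs)
  # high-specificity detections are a subset of high-sensitivity ones
  hispec <- detect_ppg_upstrokes(ppg, fp$fs, r, 3.0)
  expect_true(all(!hispec$detected | hisens$detected))
  expect_true(all(hispec$upstroke_time[hispec$detected] %in%
                    hisens$upstroke_time[hisens$detected]))
  # flat PPG -> no upstrokes
  flat <- detect_ppg_upstrokes(rep(0, 60000), 1000, seq(1, 50, 0.8), 1.5)
  expect_false(any(flat$detected))
})

test_that("PWV is the reciprocal pulse-arrival delay with flags", {
  p <- compute_pwv(c(0, 1, 2), c(0.25, 1.0, NA))
  expect_equal(p$pwv[1], 4.0)
  expect_equal(p$flag, c("ok", "invalid_delay", "no_upstroke"))
  expect_true(is.na(p$pwv[2]) && is.na(p$pwv[3]))
  neg <- compute_pwv(1, 0.9)
  expect_equal(neg$flag, "invalid_delay")
})

test_that("two-stage merge keeps only values inside the -3 SD/+5 SD band", {
  # high-specificity series: mean 4.0, SD 0.2
  set.seed(2)
  ref_vals <- c(3.8, 4.2, rep(4, 8))
  ref_vals <- (ref_vals - mean(ref_vals)) / sd(ref_vals) * 0.2 + 4
  r_times <- seq_len(12)
  hispec <- compute_pwv(r_times, r_times + 1 / c(ref_vals, 4, 4))
  hispec$pwv[11:12] <- NA; hispec$flag[11:12] <- "no_upstroke"
  hisens <- compute_pwv(r_times, r_times + 1 / c(ref_vals, 5.2, 3.5))
  merged <- merge_two_stage(hispec, hisens)
  # 5.2 > 4 + 5*0.2 -> discarded; 3.5 >= 4 - 3*0.2 -> kept
  expect_equal(merged$flag[11], "discarded_pwv")
  expect_true(is.na(merged$pwv[11]))
  expect_equal(merged$flag[12], "ok")
  expect_equal(merged$pwv[12], 3.5, tolerance = 1e-9)
  # final series is a subset of the high-sensitivity series
  expect_true(all(is.na(merged$pwv) |
                    abs(merged$pwv - hisens$pwv) < 1e-12))
  # empty high-specificity series: fallback with warning
  empty <- compute_pwv(r_times, rep(NA_real_, 12))
  expect_warning(fb <- merge_two_stage(empty, hisens), "high-specificity")
  expect_equal(fb$pwv, hisens$pwv)
})

test_that("noise-free per-beat PWV equals the reciprocal true PTT within
           one native sample", {
  p <- clean_prepared()
  s <- clean_session()
  b <- p$beats
  ok <- b$flag == "ok"
  tru <- 1 / s$truth$beats$ptt[seq_len(nrow(b))]
  ratio_err <- abs(1 / b$pwv[ok] - 1 / tru[ok])
  expect_lt(max(ratio_err), 1e-3)   # delay error below one native sample
  # the asymmetric -3 SD/+5 SD band trims part of the genuine downward
  # PWV excursion during the pressure drop, but most beats survive
  expect_gt(mean(ok), 0.7)
})

test_that("beat table carries IBI and matched BP values", {
  p <- clean_prepared()
  s <- clean_session()
  b <- p$beats
  expect_equal(b$ibi_ms[-1], diff(b$r_time) * 1000)
  expect_lt(max(abs(b$sbp - s$truth$beats$sbp[seq_len(nrow(b))]),
                na.rm = TRUE), 0.5)
})
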