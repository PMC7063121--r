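test_that("noise-free MAP trajectory is baseline-constant without a drop", {
  cfg <- sim_config(drop_magnitude_map = 0, mayer_amplitude_mmHg = 0,
                    between_subject_cv = 0)
  tr <- simulate_map_trajectory(cfg, "preferred_supine_to_stand",
                                t = seq(0, 270, by = 0.04))
  map_base <- cfg$baseline_dbp + (cfg$baseline_sbp - cfg$baseline_dbp) / 3
  expect_equal(tr$map, rep(map_base, nrow(tr)))
  expect_equal(tr$sbp, rep(cfg$baseline_sbp, nrow(tr)))
})

test_that("orthostatic drop reaches its configured nadir depth and time", {
  cfg <- sim_config(drop_magnitude_map = 25, time_to_nadir = 12,
                    mayer_amplitude_mmHg = 0, between_subject_cv = 0)
  t <- seq(0, 270, by = 0.001)
  tr <- simulate_map_trajectory(cfg, "preferred_supine_to_stand", t = t)
  onset <- cfg$baseline_s
  post <- tr[tr$t > onset & tr$t <= onset + 60, ]
  map_base <- cfg$baseline_dbp + (cfg$baseline_sbp - cfg$baseline_dbp) / 3
  i <- which.min(post$map)
  expect_equal(post$map[i], map_base - 25, tolerance = 1e-9)
  expect_equal(post$t[i] - onset, 12, tolerance = 0.002)
  # recovery settles: within 3 mmHg (12% of the drop) at 60 s post-onset
  expect_lt(abs(tr$map[t == onset + 60] - map_base), 3)
})

test_that("squat raises MAP during the squat and drops after release", {
  cfg <- sim_config(mayer_amplitude_mmHg = 0, between_subject_cv = 0)
  t <- seq(0, 270, by = 0.01)
  tr <- simulate_map_trajectory(cfg, "squat_1min", t = t)
  onset <- cfg$baseline_s
  map_base <- cfg$baseline_dbp + (cfg$baseline_sbp - cfg$baseline_dbp) / 3
  mid_squat <- tr$map[t > onset + 20 & t < onset + 40]
  expect_true(all(mid_squat > map_base + 15))
  post <- tr$map[t > onset + 60 & t <= onset + 120]
  expect_lt(min(post), map_base - 10)
})

test_that("unknown maneuver is a configuration error", {
  expect_error(sim_config(maneuvers = "backflip"), "unknown maneuver")
  cfg <- sim_config()
  expect_error(simulate_map_trajectory(cfg, "backflip"), "unknown maneuver")
})

test_that("resting SBP shows the Mayer wave at the configured frequency", {
  cfg <- sim_config(mayer_amplitude_mmHg = 3, mayer_freq_hz = 0.1,
                    between_subject_cv = 0, baseline_s = 300)
  tr <- simulate_map_trajectory(cfg, "sit_to_stand",
                                t = seq(0, 300 - 0.04, by = 0.04))
  # periodogram oracle on the resting segment
  x <- tr$sbp - mean(tr$sbp)
  sp <- stats::spec.pgram(ts(x, frequency = 25), plot = FALSE, taper = 0)
  expect_equal(sp$freq[which.max(sp$spec)], 0.1, tolerance = 0.01)
})

test_that("beat series obeys the baroreflex coupling identities", {
  # brs 0 -> constant IBI
  cfg0 <- sim_config(brs_true = 0, mayer_amplitude_mmHg = 0,
                     between_subject_cv = 0)
  tr0 <- make_trajectory(cfg0, "rapid_supine_to_stand", cfg0$baseline_s)
  b0 <- simulate_beats(cfg0, tr0)
  expect_equal(diff(range(b0$ibi_ms)), 0)
  # IBI_n = t_n - t_{n-1} exactly, beat times strictly increasing
  cfg <- sim_config(between_subject_cv = 0)
  tr <- make_trajectory(cfg, "rapid_supine_to_stand", cfg$baseline_s)
  b <- simulate_beats(cfg, tr)
  expect_true(all(diff(b$t) > 0))
  expect_equal(b$ibi_ms[-1], diff(b$t) * 1000, tolerance = 1e-9)
  # plug-in: IBI at the beat equals IBI_base - brs * (SBP_base - SBP(t))
  ibi_base <- 60000 / cfg$baseline_hr
  expect_equal(b$ibi_ms,
               ibi_base - cfg$brs_true * (cfg$baseline_sbp - b$sbp),
               tolerance = 1e-6)
})

test_that("nonphysiological IBI aborts the simulation", {
  cfg <- sim_config(brs_true = 30, drop_magnitude_map = 40,
                    between_subject_cv = 0)
  tr <- make_trajectory(cfg, "rapid_supine_to_stand", cfg$baseline_s)
  expect_error(simulate_beats(cfg, tr), "250 ms")
})

test_that("same seed and config give bit-identical sessions", {
  cfg <- sim_config(participant_count = 1,
                    noise_sd = list(ppg = 0.01, nirs = 0.2),
                    rng_seed = 9, baseline_s = 60, post_s = 60)
  s1 <- simulate_session(cfg, 1, "sit_to_stand", 1)
  s2 <- simulate_session(cfg, 1, "sit_to_stand", 1)
  expect_identical(s1$truth$beats, s2$truth$beats)
  for (j in seq_len(nrow(s1$channels)))
    expect_identical(s1$channels$samples[[j]], s2$channels$samples[[j]])
})

test_that("channel units and rates are carried in the rendering", {
  s <- clean_session()
  ch <- s$channels
  expect_setequal(
    ch$channel[ch$device == "finapres"],
    c("ecg", "bp_map", "bp_sbp", "bp_dbp"))
  expect_equal(ch$units[ch$channel == "o2hb"], "uM")
  expect_equal(ch$fs[ch$channel == "finger_ppg"], 1000)
  expect_equal(ch$fs[ch$channel == "o2hb"], 50)
  # all channels cover the same wall-clock span
  spans <- vapply(seq_len(nrow(ch)),
                  function(j) length(ch$samples[[j]]) / ch$fs[j], 0)
  expect_true(all(abs(spans - spans[1]) < 0.1))
})

test_that("O2Hb deviation tracks MAP with the configured coupling", {
  cfg <- sim_config(car_true = 0.4, between_subject_cv = 0,
                    mayer_amplitude_mmHg = 0)
  s <- simulate_session(cfg, 1, "rapid_supine_to_stand", 1)
  o2 <- get_channel(s, "o2hb")
  bp <- get_channel(s, "bp_map")
  map_base <- cfg$baseline_dbp + (cfg$baseline_sbp - cfg$baseline_dbp) / 3
  expect_equal(min(o2$x) / (min(bp$x) - map_base), 0.4, tolerance = 1e-3)
  # HHb anti-correlated with smaller gain
  hh <- get_channel(s, "hhb")
  expect_equal(hh$x, -0.3 * o2$x, tolerance = 1e-9)
})

test_that("resting beat generator encodes the requested gain and lag", {
  b <- simulate_resting_beats(duration_s = 120, gain = 8, lag = 1, seed = 4)
  expect_true(all(diff(b$t) > 0))
  # IBI_{n} = base + gain * (SBP_{n-1} - base) exactly (noise-free)
  n <- nrow(b)
  expect_equal(b$ibi_ms[2:n],
               60000 / 71 + 8 * (b$sbp[1:(n - 1)] - 130),
               tolerance = 1e-9)
})
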