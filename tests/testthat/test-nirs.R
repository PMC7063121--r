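test_that("DPF increases with age and honors a constant override", {
  expect_gt(dpf_estimate(760, 60), dpf_estimate(760, 20))
  expect_gt(dpf_estimate(850, 80), dpf_estimate(850, 30))
  expect_equal(dpf_estimate(c(760, 850), 40, override = 6), c(6, 6))
  expect_error(dpf_estimate(500, 30), "wavelength")
  expect_error(dpf_estimate(760, 120), "age")
})

test_that("DPF matches an independent transcription of the published
           polynomial", {
  # dual transcription of the general DPF equation
  oracle <- function(l, a)
    223.3 + 0.05624 * a^0.8493 - 5.723e-7 * l^3 + 0.001245 * l^2 -
      0.9025 * l
  for (l in c(690, 725, 760, 808, 850, 870))
    for (a in c(1, 18, 35.5, 62, 100))
      expect_equal(dpf_estimate(l, a), oracle(l, a), tolerance = 1e-9)
  # plausible magnitude for adult forehead NIRS
  expect_true(all(dpf_estimate(c(760, 850), 30) > 4 &
                    dpf_estimate(c(760, 850), 30) < 8))
})

test_that("MBLL inversion is exact on round trips and linear", {
  eps <- default_extinction_table(c(760, 850))
  dpf <- dpf_estimate(c(760, 850), 35)
  od0 <- mbll_forward(0, 0, eps, dpf, 3.5)
  expect_equal(unname(as.numeric(mbll_inverse(od0, eps, dpf, 3.5))),
               c(0, 0))
  set.seed(7)
  for (i in 1:100) {
    o2 <- rnorm(20, 0, 5); hh <- rnorm(20, 0, 2)
    d <- runif(1, 1, 5)
    dpf_i <- runif(2, 3, 8)
    eps_i <- eps * matrix(runif(4, 0.7, 1.3), 2)
    if (kappa(eps_i, exact = TRUE) > 1e3) next
    od <- mbll_forward(o2, hh, eps_i, dpf_i, d)
    rec <- mbll_inverse(od, eps_i, dpf_i, d)
    expect_equal(rec$o2hb, o2, tolerance = 1e-9)
    expect_equal(rec$hhb, hh, tolerance = 1e-9)
  }
})

test_that("doubling the source-detector distance halves recovered
           concentrations", {
  od <- mbll_forward(c(1, 4), c(0.5, -1), distance_cm = 3)
  half <- mbll_inverse(od, distance_cm = 6)
  full <- mbll_inverse(od, distance_cm = 3)
  expect_equal(half$o2hb, full$o2hb / 2, tolerance = 1e-12)
  expect_equal(half$hhb, full$hhb / 2, tolerance = 1e-12)
})

test_that("singular extinction matrices are rejected", {
  bad <- matrix(c(1, 1, 2, 2), 2, byrow = TRUE)
  expect_error(mbll_inverse(cbind(0.1, 0.2), bad, c(6, 6), 3.5))
})

test_that("simulator optical densities invert to the planted hemoglobin
           traces", {
  cfg <- sim_config(participant_count = 1, between_subject_cv = 0,
                    nirs_emit_od = TRUE, baseline_s = 60, post_s = 60,
                    rng_seed = 3)
  s <- simulate_session(cfg, 1, "sit_to_stand", 1)
  od <- cbind(get_channel(s, "od_760")$x, get_channel(s, "od_850")$x)
  dpf <- dpf_estimate(c(760, 850), s$truth$age)
  rec <- mbll_inverse(od, default_extinction_table(c(760, 850)), dpf,
                      cfg$nirs_distance_cm)
  expect_equal(rec$o2hb, get_channel(s, "o2hb")$x, tolerance = 1e-9)
  expect_equal(rec$hhb, get_channel(s, "hhb")$x, tolerance = 1e-9)
})
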