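# Ground-truth hemodynamic simulator.
#
# Every repeat is built from deterministic closures for the continuous
# MAP/SBP/DBP trajectories; beats, channels and noise draw from RNG streams
# derived from the master seed and a per-channel key, so enabling noise on
# one channel never shifts another.

# Solve the fast time constant of the double-exponential orthostatic
# response g(t) = exp(-t/tau_rec) - exp(-t/tau_fast) so its peak sits at
# `t_nadir`, then return the template normalized to peak 1.
make_drop_template <- function(t_nadir, tau_rec) {
  peak_time <- function(tau_fast)
    log(tau_rec / tau_fast) / (1 / tau_fast - 1 / tau_rec)
  tau_fast <- stats::uniroot(function(tf) peak_time(tf) - t_nadir,
                             c(1e-4, tau_rec * 0.9999),
                             tol = 1e-12)$root
  g0 <- function(t) exp(-t / tau_rec) - exp(-t / tau_fast)
  gmax <- g0(t_nadir)
  function(t) ifelse(t > 0, g0(pmax(t, 0)) / gmax, 0)
}

# Smooth 0->1 ramp of duration `w` (integrated-cosine edge).
smooth_step <- function(t, w) {
  u <- pmin(pmax(t / w, 0), 1)
  (1 - cos(pi * u)) / 2
}

# Deterministic trajectory closures for one repeat. Deviations are shared by
# MAP/SBP/DBP with fixed ratios (SBP swings 1.2x the MAP deviation, DBP
# 0.9x) so that MAP = DBP + (SBP - DBP)/3 holds identically.
make_trajectory <- function(params, maneuver, onset, mayer_phase = 0) {
  info <- maneuver_info(maneuver)
  drop <- params$drop_magnitude_map * info$drop_scale
  g <- make_drop_template(params$time_to_nadir, params$recovery_tau)
  mayer <- function(t)
    params$mayer_amplitude_mmHg *
      sin(2 * pi * params$mayer_freq_hz * t + mayer_phase)
  if (info$squat) {
    rise <- params$squat_rise_map
    release <- onset + 60
    dev <- function(t) {
      plateau <- rise * smooth_step(t - onset, 4) *
        (1 - smooth_step(t - release, 4))
      plateau - drop * g(t - release)
    }
  } else {
    dev <- function(t) -drop * g(t - onset)
  }
  map_base <- params$baseline_dbp +
    (params$baseline_sbp - params$baseline_dbp) / 3
  list(
    map = function(t) map_base + dev(t) + mayer(t),
    sbp = function(t) params$baseline_sbp + 1.2 * (dev(t) + mayer(t)),
    dbp = function(t) params$baseline_dbp + 0.9 * (dev(t) + mayer(t)),
    map_base = map_base,
    sbp_base = params$baseline_sbp,
    dbp_base = params$baseline_dbp,
    dev = dev
  )
}

#' Simulate continuous MAP/SBP/DBP trajectories
#'
#' Noise-free arterial-pressure trajectories for one postural change:
#' constant baseline plus a Mayer-wave oscillation, then a double-exponential
#' drop/recovery after movement onset (nadir `drop_magnitude_map *
#' drop_scale` mmHg below baseline at `time_to_nadir` s, steady state by
#' 60 s). The 1-min squat instead shows a smooth plateau rise during the
#' squat and the orthostatic drop after release.
#'
#' @param config an [sim_config()] object.
#' @param maneuver maneuver name, see [maneuver_table()].
#' @param t numeric vector of times (s); movement onset is at
#'   `config$baseline_s`.
#' @param onset onset time (s), default `config$baseline_s`.
#' @param mayer_phase Mayer-wave phase, radians.
#' @return tibble with columns `t`, `map`, `sbp`, `dbp` (mmHg).
#' @export
#' @examples
#' cfg <- sim_config()
#' tr <- simulate_map_trajectory(cfg, "rapid_supine_to_stand",
#'                               t = seq(0, 200, by = 0.04))
#' range(tr$map)
simulate_map_trajectory <- function(config, maneuver,
                                    t = seq(0, config$baseline_s +
                                              config$post_s, by = 0.01),
                                    onset = config$baseline_s,
                                    mayer_phase = 0) {
  stopifnot(inherits(config, "ortho_sim_config"))
  tr <- make_trajectory(config, maneuver, onset, mayer_phase)
  tibble::tibble(t = t, map = tr$map(t), sbp = tr$sbp(t), dbp = tr$dbp(t))
}

#' Simulate a baroreflex-coupled beat series
#'
#' Places heartbeats along an SBP trajectory with the inter-beat interval
#' linearly coupled to SBP at the beat time:
#' `IBI_n = IBI_base - brs_true * (SBP_base - SBP(t_n)) + noise`, the next
#' beat following at `t_{n-1} + IBI_n`. Because `t_n` itself depends on
#' `IBI_n`, each beat is resolved by a short fixed-point iteration. Per-beat
#' SBP/DBP/MAP and the pulse transit time
#' `PTT_n = ptt_intercept + ptt_slope * SBP_n` are attached.
#'
#' @param config an [sim_config()] object (fields `brs_true`,
#'   `baseline_hr`, `ptt_*`, `ibi_noise_sd_ms`, `ptt_noise_sd_s`).
#' @param trajectory either the tibble returned by
#'   [simulate_map_trajectory()] or a list of closures `sbp`, `dbp`, `map`.
#' @param duration_s time span to cover, s.
#' @param seed RNG seed for the beat-level noise streams.
#' @return tibble with columns `t` (s), `ibi_ms`, `sbp`, `dbp`, `map`
#'   (mmHg), `ptt` (s); strictly increasing `t` with
#'   `ibi_ms[n] = 1000 * (t[n] - t[n-1])` exactly.
#' @export
simulate_beats <- function(config, trajectory,
                           duration_s = NULL, seed = config$rng_seed) {
  stopifnot(inherits(config, "ortho_sim_config"))
  if (is.data.frame(trajectory)) {
    if (is.null(duration_s)) duration_s <- max(trajectory$t)
    sbp_f <- stats::approxfun(trajectory$t, trajectory$sbp, rule = 2)
    dbp_f <- stats::approxfun(trajectory$t, trajectory$dbp, rule = 2)
    map_f <- stats::approxfun(trajectory$t, trajectory$map, rule = 2)
  } else {
    if (is.null(duration_s))
      duration_s <- config$baseline_s + config$post_s
    sbp_f <- trajectory$sbp; dbp_f <- trajectory$dbp; map_f <- trajectory$map
  }
  ibi_base <- 60000 / config$baseline_hr
  brs <- config$brs_true
  sbp_base <- config$baseline_sbp
  n_max <- ceiling(duration_s / (0.25))
  t <- numeric(n_max); ibi <- numeric(n_max)
  with_seed(derive_seed(seed, "beats"), {
    ibi_noise <- rnorm(n_max, 0, config$ibi_noise_sd_ms)
    ptt_noise <- rnorm(n_max, 0, config$ptt_noise_sd_s)
    t_prev <- 0
    n <- 0L
    repeat {
      # fixed-point resolution of t_n = t_{n-1} + IBI(SBP(t_n))/1000
      ib <- ibi_base
      for (it in 1:12)
        ib <- ibi_base - brs * (sbp_base - sbp_f(t_prev + ib / 1000)) +
          ibi_noise[n + 1L]
      if (ib < 250)
        rlang::abort(sprintf(
          "simulated IBI %.0f ms below the 250 ms physiological floor", ib))
      t_new <- t_prev + ib / 1000
      if (t_new > duration_s) break
      n <- n + 1L
      t[n] <- t_new; ibi[n] <- ib
      t_prev <- t_new
    }
    sbp_n <- sbp_f(t[seq_len(n)])
    tibble::tibble(
      t = t[seq_len(n)],
      ibi_ms = ibi[seq_len(n)],
      sbp = sbp_n,
      dbp = dbp_f(t[seq_len(n)]),
      map = map_f(t[seq_len(n)]),
      ptt = config$ptt_intercept + config$ptt_slope * sbp_n +
        ptt_noise[seq_len(n)]
    )
  })
}

# --- PPG pulse template ----------------------------------------------------

# Gamma-like systolic pulse, 0.25 s wide, peak amplitude 1.
ppg_pulse_shape <- function(u) {
  tau <- 0.05
  v <- ifelse(u > 0 & u < 0.25, (u / tau)^2 * exp(-u / tau), 0)
  v / ((2)^2 * exp(-2))   # peak at u = 2*tau
}

.template_cache <- new.env(parent = emptyenv())

# Offset between a pulse's placement origin and the location of the peak of
# the first derivative of the band-passed pulse, as seen by the upstroke
# detector at rate `fs`. Rendering subtracts this so that ground-truth PTT
# is exactly the R-peak-to-derivative-peak delay the PWV stage measures.
pulse_upstroke_offset <- function(fs) {
  key <- paste0("off", fs)
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  n <- round(20 * fs)
  t <- (seq_len(n) - 1) / fs
  x <- ppg_pulse_shape(t - 10)
  xf <- bandpass_ppg(x, fs)
  d <- diff(xf)
  i <- which.max(d)
  off <- t[i] - 10
  .template_cache[[key]] <- off
  off
}

# --- channel rendering -----------------------------------------------------

add_pulses <- function(samples, t_grid, starts, amps, shape, width, fs) {
  n <- length(samples)
  t0 <- t_grid[1]
  step <- if (n > 1) t_grid[2] - t_grid[1] else 1 / fs
  for (j in seq_along(starts)) {
    i0 <- max(1L, floor((starts[j] - t0) / step) + 1L)
    i1 <- min(n, ceiling((starts[j] + width - t0) / step) + 1L)
    if (i0 > n || i1 < 1L) next
    idx <- i0:i1
    samples[idx] <- samples[idx] + amps[j] * shape(t_grid[idx] - starts[j])
  }
  samples
}

ecg_spike_shape <- function(u) {
  # triangular R wave, 20 ms base, apex 10 ms into the template window
  w <- 0.01
  pmax(0, 1 - abs(u - w) / w)
}

# Map a device-clock sample grid to reference time.
device_to_ref <- function(t_dev, offset, drift_ppm) {
  (t_dev - offset) / (1 + drift_ppm * 1e-6)
}

#' Render multimodal channels from a simulated beat series
#'
#' Produces the per-device channel set for one repeat: finger/wrist PPG at
#' native rate (per-beat amplitude-modulated pulses over a MAP-coupled
#' envelope), an ECG R-wave impulse train, continuous BP waveforms plus
#' Finapres-style per-beat SBP/DBP/MAP events, NIRS O2Hb/HHb (and optionally
#' raw two-wavelength optical densities through the forward modified
#' Beer-Lambert model), a trunk-tilt channel, and the shared pulse-train
#' sync reference, with per-device clock offsets/drifts applied.
#'
#' @param truth beat tibble from [simulate_beats()].
#' @param config an [sim_config()] object.
#' @param trajectory closure list from the internal trajectory builder or a
#'   trajectory tibble (continuous MAP is needed for the NIRS forward model).
#' @param maneuver maneuver name.
#' @param onset movement onset, s.
#' @param participant participant id (used for the NIRS age-dependent DPF
#'   and for RNG stream derivation).
#' @param age participant age in years (DPF estimation).
#' @param seed master seed for the channel noise streams.
#' @return A list of class `ortho_session`; `$channels` is a tibble with one
#'   row per channel (`device`, `channel`, `fs`, `units`, `samples`
#'   list-column), `$bp_beats` the per-beat BP event table, `$truth` the
#'   ground truth.
#' @export
render_channels <- function(truth, config, trajectory, maneuver,
                            onset = config$baseline_s,
                            participant = 1L, age = 30,
                            seed = config$rng_seed) {
  stopifnot(inherits(config, "ortho_sim_config"))
  if (is.data.frame(trajectory)) {
    trajectory <- list(
      map = stats::approxfun(trajectory$t, trajectory$map, rule = 2),
      sbp = stats::approxfun(trajectory$t, trajectory$sbp, rule = 2),
      dbp = stats::approxfun(trajectory$t, trajectory$dbp, rule = 2),
      map_base = config$baseline_dbp +
        (config$baseline_sbp - config$baseline_dbp) / 3)
  }
  dur <- config$baseline_s + config$post_s
  offs <- config$device_clock_offsets
  drifts <- config$device_clock_drift_ppm
  noise <- config$noise_sd
  chan_seed <- function(key) derive_seed(seed, paste0("chan/", key))

  grid <- function(fs) (seq_len(round(dur * fs)) - 1) / fs

  # ---- beat-dependent quantities ----
  n_beats <- nrow(truth)
  artifact <- rep(FALSE, n_beats)
  if (config$artifact_beat_fraction > 0) {
    artifact <- with_seed(chan_seed("artifact_beats"),
      runif(n_beats) < config$artifact_beat_fraction)
  }
  truth$artifact_beat <- artifact

  render_ppg <- function(key, gain_factor, extra_delay) {
    fs <- config$ppg_fs
    t_dev <- grid(fs)
    t_ref <- device_to_ref(t_dev, offs$ppg, drifts$ppg)
    # perfusion envelope follows the continuous MAP; pulse amplitudes are
    # modulated per beat
    env <- 1 + config$ppg_gain * gain_factor * trajectory$map(t_ref)
    x <- env
    pf <- config$ppg_pulsatile_fraction
    if (pf > 0) {
      delta <- pulse_upstroke_offset(fs)
      amp <- pf * config$ppg_gain * gain_factor * truth$map * 0.6
      starts <- truth$t + truth$ptt + extra_delay - delta
      ok <- !truth$artifact_beat
      x <- add_pulses(x, t_ref, starts[ok], amp[ok],
                      ppg_pulse_shape, 0.25, fs)
      if (any(truth$artifact_beat)) {
        a_starts <- truth$t[truth$artifact_beat] +
          config$artifact_beat_delay_s - delta
        x <- add_pulses(x, t_ref, a_starts,
                        0.45 * amp[truth$artifact_beat],
                        ppg_pulse_shape, 0.25, fs)
      }
    }
    if (noise$ppg > 0)
      x <- x + with_seed(chan_seed(key), rnorm(length(x), 0, noise$ppg))
    x
  }

  finger <- render_ppg("finger_ppg", 1, 0)
  wrist  <- render_ppg("wrist_ppg", 0.8, 0.02)

  # ---- ECG ----
  t_ecg <- grid(config$ecg_fs)
  t_ecg_ref <- device_to_ref(t_ecg, offs$finapres, drifts$finapres)
  # symmetric triangular R wave: place the template window around the apex
  ecg <- add_pulses(numeric(length(t_ecg)), t_ecg_ref, truth$t - 0.01,
                    rep(1, n_beats), ecg_spike_shape, 0.02, config$ecg_fs)
  if (noise$ecg > 0)
    ecg <- ecg + with_seed(chan_seed("ecg"),
                           rnorm(length(ecg), 0, noise$ecg))

  # ---- continuous BP waveforms + per-beat events ----
  t_bpw <- grid(config$bp_wave_fs)
  t_bpw_ref <- device_to_ref(t_bpw, offs$finapres, drifts$finapres)
  bp_noise <- function(key, n)
    if (noise$bp > 0) with_seed(chan_seed(key), rnorm(n, 0, noise$bp))
    else numeric(n)
  bp_map <- trajectory$map(t_bpw_ref) + bp_noise("bp_map", length(t_bpw))
  bp_sbp <- trajectory$sbp(t_bpw_ref) + bp_noise("bp_sbp", length(t_bpw))
  bp_dbp <- trajectory$dbp(t_bpw_ref) + bp_noise("bp_dbp", length(t_bpw))
  bp_beats <- tibble::tibble(
    t = truth$t * (1 + drifts$finapres * 1e-6) + offs$finapres,
    sbp = truth$sbp + bp_noise("bp_sbp_ev", n_beats),
    dbp = truth$dbp + bp_noise("bp_dbp_ev", n_beats),
    map = truth$map + bp_noise("bp_map_ev", n_beats)
  )

  # ---- NIRS ----
  t_nirs <- grid(config$nirs_fs)
  t_nirs_ref <- device_to_ref(t_nirs, offs$nirs, drifts$nirs)
  map_dev_nirs <- trajectory$map(t_nirs_ref) - trajectory$map_base
  o2hb_clean <- config$car_true_participant %||% config$car_true
  o2hb_clean <- o2hb_clean * map_dev_nirs
  hhb_clean <- config$hhb_ratio * o2hb_clean
  nirs_noise <- function(key)
    if (noise$nirs > 0)
      with_seed(chan_seed(key), rnorm(length(t_nirs), 0, noise$nirs))
    else numeric(length(t_nirs))
  o2hb <- o2hb_clean + nirs_noise("o2hb")
  hhb <- hhb_clean + nirs_noise("hhb")

  # ---- tilt ----
  info <- maneuver_info(maneuver)
  t_tilt <- grid(config$tilt_fs)
  t_tilt_ref <- device_to_ref(t_tilt, offs$tilt, drifts$tilt)
  ang <- info$angle_from +
    (info$angle_to - info$angle_from) *
      smooth_step(t_tilt_ref - onset, info$transition_s)
  if (info$squat)   # return to standing after the 1-min squat
    ang <- ang + (info$angle_from - info$angle_to) *
      smooth_step(t_tilt_ref - (onset + 60), info$transition_s)
  if (noise$tilt > 0)
    ang <- ang + with_seed(chan_seed("tilt"),
                           rnorm(length(ang), 0, noise$tilt))

  rows <- list(
    list("ppg", "finger_ppg", config$ppg_fs, "a.u.", finger),
    list("ppg", "wrist_ppg", config$ppg_fs, "a.u.", wrist),
    list("finapres", "ecg", config$ecg_fs, "a.u.", ecg),
    list("finapres", "bp_map", config$bp_wave_fs, "mmHg", bp_map),
    list("finapres", "bp_sbp", config$bp_wave_fs, "mmHg", bp_sbp),
    list("finapres", "bp_dbp", config$bp_wave_fs, "mmHg", bp_dbp),
    list("nirs", "o2hb", config$nirs_fs, "uM", o2hb),
    list("nirs", "hhb", config$nirs_fs, "uM", hhb),
    list("tilt", "tilt", config$tilt_fs, "deg", ang)
  )

  if (config$nirs_emit_od) {
    eps <- default_extinction_table(config$nirs_wavelengths_nm)
    dpf <- dpf_estimate(config$nirs_wavelengths_nm, age)
    od <- mbll_forward(o2hb, hhb, eps, dpf, config$nirs_distance_cm)
    rows <- c(rows, list(
      list("nirs", paste0("od_", config$nirs_wavelengths_nm[1]),
           config$nirs_fs, "OD", od[, 1]),
      list("nirs", paste0("od_", config$nirs_wavelengths_nm[2]),
           config$nirs_fs, "OD", od[, 2])
    ))
  }

  if (config$sync) {
    n_min <- ceiling(dur / 60)
    for (dev in c("ppg", "finapres", "nirs", "tilt")) {
      fs <- switch(dev, ppg = config$ppg_fs, finapres = config$ecg_fs,
                   nirs = config$nirs_fs, tilt = config$tilt_fs)
      t_dev <- grid(fs)
      t_ref <- device_to_ref(t_dev, offs[[dev]], drifts[[dev]])
      rows <- c(rows, list(list(dev, "sync", fs, "binary",
                                sync_wave(t_ref))))
    }
  }

  channels <- tibble::tibble(
    device = vapply(rows, `[[`, "", 1),
    channel = vapply(rows, `[[`, "", 2),
    fs = vapply(rows, `[[`, 0, 3),
    units = vapply(rows, `[[`, "", 4),
    samples = lapply(rows, `[[`, 5)
  )

  # planted flat/missing dropout segments
  if (!is.null(config$artifact_spec) && nrow(config$artifact_spec) > 0) {
    for (i in seq_len(nrow(config$artifact_spec))) {
      a <- config$artifact_spec[i, ]
      j <- which(channels$channel == a$channel)
      if (!length(j)) next
      fs <- channels$fs[j]
      x <- channels$samples[[j]]
      i0 <- max(1L, floor((onset + a$start_s) * fs) + 1L)
      i1 <- min(length(x), ceiling((onset + a$start_s + a$duration_s) * fs))
      if (i0 <= i1) {
        # NIRS/BP dropouts are missing samples; PPG/ECG dropouts flatline
        # at the last value (a hard step would ring through the 0.05-Hz
        # high-pass for seconds)
        x[i0:i1] <- if (a$channel %in% c("o2hb", "hhb", "bp_map",
                                         "bp_sbp", "bp_dbp")) NA_real_
                    else x[i0]
      }
      channels$samples[[j]] <- x
    }
    # BP events: drop beats inside a bp_map dropout
    bp_art <- config$artifact_spec[
      config$artifact_spec$channel == "bp_map", , drop = FALSE]
    if (nrow(bp_art)) {
      keep <- rep(TRUE, nrow(bp_beats))
      for (i in seq_len(nrow(bp_art)))
        keep <- keep & !(bp_beats$t >= onset + bp_art$start_s[i] &
                         bp_beats$t <= onset + bp_art$start_s[i] +
                           bp_art$duration_s[i])
      bp_beats <- bp_beats[keep, ]
    }
  }

  session <- list(
    participant = participant,
    maneuver = maneuver,
    rep_idx = 1L,
    channels = channels,
    bp_beats = bp_beats,
    pre_aligned = all(unlist(offs) == 0) && all(unlist(drifts) == 0),
    truth = list(
      onset = onset,
      beats = truth,
      brs_true = config$brs_true,
      car_true = config$car_true_participant %||% config$car_true,
      age = age
    ),
    meta = list(offsets = offs, drifts = drifts, duration_s = dur)
  )
  class(session) <- "ortho_session"
  session
}

#' @export
print.ortho_session <- function(x, ...) {
  cat(sprintf(
    "<ortho_session> participant %s, %s, repeat %d: %d channels, %d beats\n",
    x$participant, x$maneuver, x$rep_idx, nrow(x$channels),
    nrow(x$truth$beats)))
  invisible(x)
}

# Per-participant physiological parameters: multiplicative between-subject
# spread on baselines, drop magnitude and the BRS/CAR couplings, plus an age
# draw used for the NIRS pathlength factor.
participant_params <- function(config, participant) {
  cv <- config$between_subject_cv
  with_seed(derive_seed(config$rng_seed, paste0("participant/", participant)), {
    # truncated multiplicative spread (z clipped at +/-2)
    f <- function(x) x * (1 + cv * pmax(-2, pmin(2, rnorm(1))))
    p <- config
    map_b <- config$baseline_dbp +
      (config$baseline_sbp - config$baseline_dbp) / 3
    map_b2 <- f(map_b)
    pp2 <- f(config$baseline_sbp - config$baseline_dbp)
    p$baseline_sbp <- map_b2 + 2 / 3 * pp2
    p$baseline_dbp <- map_b2 - 1 / 3 * pp2
    p$baseline_hr <- f(config$baseline_hr)
    p$drop_magnitude_map <- f(config$drop_magnitude_map)
    p$brs_true <- f(config$brs_true)
    p$car_true_participant <- f(config$car_true)
    p$age <- runif(1, 20, 60)
    # baroreflex saturation: cap the gain so the worst-case SBP drop over
    # the configured maneuvers cannot push IBI below ~300 ms
    max_scale <- max(maneuver_table()$drop_scale[
      maneuver_table()$maneuver %in% config$maneuvers], 1)
    worst_sbp_drop <- 1.2 * (p$drop_magnitude_map * max_scale +
                               p$mayer_amplitude_mmHg)
    ibi_base <- 60000 / p$baseline_hr
    brs_cap <- (ibi_base - 300) / worst_sbp_drop
    p$brs_true <- min(p$brs_true, brs_cap)
    p
  })
}

#' Simulate one session (participant x maneuver x repeat)
#'
#' @param config an [sim_config()] object.
#' @param participant participant index (drives between-subject variation).
#' @param maneuver maneuver name.
#' @param rep_idx repeat index (drives Mayer phase and noise streams).
#' @return An `ortho_session` (see [render_channels()]); `$truth` carries the
#'   participant's true BRS/CAR, beat table and onset.
#' @export
#' @examples
#' s <- simulate_session(sim_config(rng_seed = 7), 1,
#'                       "rapid_supine_to_stand", 1)
#' s
simulate_session <- function(config, participant, maneuver, rep_idx = 1L) {
  params <- participant_params(config, participant)
  rep_key <- sprintf("rep/%s/%s/%d", participant, maneuver, rep_idx)
  rep_seed <- derive_seed(config$rng_seed, rep_key)
  mayer_phase <- with_seed(derive_seed(rep_seed, "mayer"),
                           runif(1, 0, 2 * pi))
  onset <- config$baseline_s
  tr <- make_trajectory(params, maneuver, onset, mayer_phase)
  truth <- simulate_beats(params, tr, seed = rep_seed)
  ses <- render_channels(truth, params, tr, maneuver, onset = onset,
                         participant = participant, age = params$age,
                         seed = rep_seed)
  ses$rep_idx <- as.integer(rep_idx)
  ses$truth$brs_true <- params$brs_true
  ses$truth$car_true <- params$car_true_participant
  ses$truth$mayer_phase <- mayer_phase
  ses
}

#' Simulate a cohort
#'
#' @param config an [sim_config()] object; `participant_count`,
#'   `repeats_per_maneuver` and `maneuvers` define the grid.
#' @return tibble with columns `participant`, `maneuver`, `rep_idx` and a
#'   `session` list-column of `ortho_session` objects.
#' @export
simulate_cohort <- function(config) {
  grid <- tidyr::expand_grid(
    participant = seq_len(config$participant_count),
    maneuver = config$maneuvers,
    rep_idx = seq_len(config$repeats_per_maneuver)
  )
  grid$session <- purrr::pmap(grid, function(participant, maneuver, rep_idx)
    simulate_session(config, participant, maneuver, rep_idx))
  grid
}

#' Simulate a resting beat series with Mayer-wave baroreflex coupling
#'
#' Spontaneous resting SBP oscillates with the Mayer wave; the inter-beat
#' interval follows with a configurable gain and beat lag:
#' `IBI_n = IBI_base + gain * (SBP_{n-lag} - SBP_base) + noise`. Used for
#' sequence-method BRS/BEI analysis of resting epochs.
#'
#' @param duration_s epoch length, s (default 300, a 5-min resting epoch).
#' @param sbp_base,hr_base baseline SBP (mmHg) and heart rate (bpm).
#' @param gain baroreflex gain, ms/mmHg.
#' @param lag beat lag of the IBI response.
#' @param mayer_amplitude,mayer_freq SBP oscillation amplitude (mmHg) and
#'   frequency (Hz).
#' @param sbp_noise_sd,ibi_noise_sd additive per-beat noise SDs.
#' @param seed RNG seed.
#' @return tibble with `t` (s), `sbp` (mmHg), `ibi_ms`.
#' @export
simulate_resting_beats <- function(duration_s = 300, sbp_base = 130,
                                   hr_base = 71, gain = 8, lag = 1,
                                   mayer_amplitude = 3, mayer_freq = 0.1,
                                   sbp_noise_sd = 0, ibi_noise_sd = 0,
                                   seed = 1) {
  ibi_base <- 60000 / hr_base
  n_max <- ceiling(duration_s / 0.25) + lag + 1
  with_seed(seed, {
    phase <- runif(1, 0, 2 * pi)
    sbp_noise <- rnorm(n_max, 0, sbp_noise_sd)
    ibi_noise <- rnorm(n_max, 0, ibi_noise_sd)
    t <- numeric(n_max); sbp <- numeric(n_max); ibi <- numeric(n_max)
    t_prev <- 0; n <- 0L
    repeat {
      idx <- n + 1L
      sbp_prev_lag <- if (idx - lag >= 1L) sbp[idx - lag] else sbp_base
      ib <- ibi_base + gain * (sbp_prev_lag - sbp_base) + ibi_noise[idx]
      t_new <- t_prev + ib / 1000
      if (t_new > duration_s || idx > n_max) break
      t[idx] <- t_new
      ibi[idx] <- ib
      sbp[idx] <- sbp_base +
        mayer_amplitude * sin(2 * pi * mayer_freq * t_new + phase) +
        sbp_noise[idx]
      n <- idx
      t_prev <- t_new
    }
    tibble::tibble(t = t[seq_len(n)], sbp = sbp[seq_len(n)],
                   ibi_ms = ibi[seq_len(n)])
  })
}
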