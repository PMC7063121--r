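#' Maneuver catalogue
#'
#' Postural-change types supported by the simulator and the pipeline, with the
#' transition profile used for the trunk-tilt channel and the scaling applied
#' to the orthostatic MAP drop. Transition durations are cohort medians for
#' healthy adults; the head-up-tilt response is attenuated relative to active
#' standing, and the 1-min squat is a BP-raising maneuver followed by a
#' post-release drop.
#'
#' @return A tibble with one row per maneuver: `maneuver`, `transition_s`
#'   (movement duration, s), `angle_from`/`angle_to` (trunk angle, degrees from
#'   horizontal), `drop_scale` (multiplier on `drop_magnitude_map`), and
#'   `squat` (logical).
#' @export
#' @examples
#' maneuver_table()
maneuver_table <- function() {
  tibble::tribble(
    ~maneuver,                    ~transition_s, ~angle_from, ~angle_to, ~drop_scale, ~squat,
    "sit_to_stand",               7.0,           75,          90,        0.8,         FALSE,
    "slow_supine_to_stand",       15.6,          0,           90,        0.9,         FALSE,
    "preferred_supine_to_stand",  9.0,           0,           90,        1.0,         FALSE,
    "rapid_supine_to_stand",      6.7,           0,           90,        1.2,         FALSE,
    "head_up_tilt",               16.4,          0,           70,        0.4,         FALSE,
    "squat_1min",                 3.0,           90,          70,        1.0,         TRUE
  )
}

maneuver_info <- function(maneuver) {
  tab <- maneuver_table()
  row <- tab[tab$maneuver == maneuver, ]
  if (nrow(row) != 1L)
    rlang::abort(sprintf(
      "unknown maneuver '%s' (see maneuver_table())", maneuver))
  as.list(row)
}

#' Simulation configuration
#'
#' Builds the parameter set for the ground-truth hemodynamic simulator. The
#' defaults describe a healthy-adult cohort: resting SBP/DBP 130/82 mmHg and
#' heart rate 71 bpm (cohort medians), an orthostatic MAP drop of 25 mmHg
#' reaching its nadir 12 s after movement onset and recovering with a 15-s
#' time constant (steady state by 60 s), Mayer waves of 3 mmHg at 0.1 Hz,
#' baroreflex gain 8 ms/mmHg, cerebral autoregulation coupling 0.4 uM/mmHg,
#' and a pulse transit time linearly (negatively) coupled to SBP.
#'
#' @param participant_count number of simulated participants.
#' @param repeats_per_maneuver repeats per postural change.
#' @param maneuvers character vector of maneuvers (see [maneuver_table()]).
#' @param baseline_sbp,baseline_dbp baseline systolic/diastolic BP, mmHg.
#' @param baseline_hr baseline heart rate, bpm.
#' @param drop_magnitude_map orthostatic MAP drop at nadir, mmHg (before the
#'   per-maneuver `drop_scale`).
#' @param time_to_nadir time from movement onset to the BP nadir, s (< 30).
#' @param recovery_tau recovery time constant, s.
#' @param squat_rise_map MAP plateau rise during the 1-min squat, mmHg.
#' @param brs_true baroreflex gain, ms IBI per mmHg SBP.
#' @param car_true cerebral autoregulation coupling, uM O2Hb per mmHg MAP.
#' @param hhb_ratio HHb deviation as a (negative) fraction of the O2Hb
#'   deviation.
#' @param ptt_intercept,ptt_slope pulse-transit-time model
#'   PTT = intercept + slope * SBP, s and s/mmHg (`ptt_slope` < 0).
#' @param ppg_gain PPG envelope gain, a.u. per mmHg MAP.
#' @param ppg_pulsatile_fraction amplitude of the pulsatile PPG component
#'   relative to its default; 0 renders an envelope-only PPG that is exactly
#'   affine in per-beat MAP.
#' @param mayer_amplitude_mmHg,mayer_freq_hz Mayer-wave amplitude and
#'   frequency.
#' @param ibi_noise_sd_ms per-beat IBI noise, ms.
#' @param ptt_noise_sd_s per-beat PTT noise, s.
#' @param noise_sd named list of additive sensor-noise SDs per channel class
#'   (`ppg` a.u., `ecg` a.u., `nirs` uM, `bp` mmHg, `tilt` degrees).
#' @param between_subject_cv coefficient of variation for between-participant
#'   spread of baselines, drop magnitude, BRS and CAR.
#' @param device_clock_offsets named list of clock offsets (s) for devices
#'   `ppg`, `finapres`, `nirs`, `tilt`.
#' @param device_clock_drift_ppm named list of linear clock drifts, parts per
#'   million.
#' @param artifact_spec data frame with columns `channel`, `start_s`
#'   (relative to movement onset), `duration_s`: flat/missing dropout
#'   segments.
#' @param artifact_beat_fraction fraction of beats whose PPG pulse is replaced
#'   by a small premature deflection (arriving 40 ms after the R-peak) that
#'   only the sensitive upstroke threshold detects.
#' @param artifact_beat_delay_s arrival delay of those artifact deflections.
#' @param baseline_s pre-onset recording duration, s (>= 60).
#' @param post_s post-onset recording duration, s.
#' @param ppg_fs,ecg_fs,nirs_fs,bp_fs,tilt_fs native sampling rates, Hz.
#' @param bp_wave_fs sampling rate of the continuous BP waveform channels.
#' @param sync logical; render the shared pulse-train reference channel.
#' @param nirs_emit_od logical; also emit raw two-wavelength optical densities
#'   through the forward modified Beer-Lambert model.
#' @param nirs_wavelengths_nm two NIRS wavelengths, nm.
#' @param nirs_distance_cm source-detector distance, cm.
#' @param rng_seed master seed; every channel/repeat derives its own stream.
#' @return A list of class `ortho_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(participant_count = 2, rng_seed = 1)
#' cfg$brs_true
sim_config <- function(participant_count = 8,
                       repeats_per_maneuver = 3,
                       maneuvers = "rapid_supine_to_stand",
                       baseline_sbp = 130,
                       baseline_dbp = 82,
                       baseline_hr = 71,
                       drop_magnitude_map = 25,
                       time_to_nadir = 12,
                       recovery_tau = 15,
                       squat_rise_map = 20,
                       brs_true = 8,
                       car_true = 0.4,
                       hhb_ratio = -0.3,
                       ptt_intercept = 0.35,
                       ptt_slope = -8e-4,
                       ppg_gain = 0.02,
                       ppg_pulsatile_fraction = 1,
                       mayer_amplitude_mmHg = 3,
                       mayer_freq_hz = 0.1,
                       ibi_noise_sd_ms = 0,
                       ptt_noise_sd_s = 0,
                       noise_sd = list(),
                       between_subject_cv = 0.2,
                       device_clock_offsets = list(),
                       device_clock_drift_ppm = list(),
                       artifact_spec = NULL,
                       artifact_beat_fraction = 0,
                       artifact_beat_delay_s = 0.04,
                       baseline_s = 90,
                       post_s = 180,
                       ppg_fs = 1000, ecg_fs = 1000, nirs_fs = 50,
                       bp_fs = 1000, tilt_fs = 50,
                       bp_wave_fs = 1000,
                       sync = FALSE,
                       nirs_emit_od = FALSE,
                       nirs_wavelengths_nm = c(760, 850),
                       nirs_distance_cm = 3.5,
                       rng_seed = 1L) {
  noise_default <- list(ppg = 0, ecg = 0, nirs = 0, bp = 0, tilt = 0)
  noise_sd <- utils::modifyList(noise_default, as.list(noise_sd))
  off_default <- list(ppg = 0, finapres = 0, nirs = 0, tilt = 0)
  device_clock_offsets <- utils::modifyList(off_default,
                                            as.list(device_clock_offsets))
  drift_default <- list(ppg = 0, finapres = 0, nirs = 0, tilt = 0)
  device_clock_drift_ppm <- utils::modifyList(drift_default,
                                              as.list(device_clock_drift_ppm))
  cfg <- list(
    participant_count = as.integer(participant_count),
    repeats_per_maneuver = as.integer(repeats_per_maneuver),
    maneuvers = maneuvers,
    baseline_sbp = baseline_sbp, baseline_dbp = baseline_dbp,
    baseline_hr = baseline_hr,
    drop_magnitude_map = drop_magnitude_map,
    time_to_nadir = time_to_nadir, recovery_tau = recovery_tau,
    squat_rise_map = squat_rise_map,
    brs_true = brs_true, car_true = car_true, hhb_ratio = hhb_ratio,
    ptt_intercept = ptt_intercept, ptt_slope = ptt_slope,
    ppg_gain = ppg_gain,
    ppg_pulsatile_fraction = ppg_pulsatile_fraction,
    mayer_amplitude_mmHg = mayer_amplitude_mmHg,
    mayer_freq_hz = mayer_freq_hz,
    ibi_noise_sd_ms = ibi_noise_sd_ms, ptt_noise_sd_s = ptt_noise_sd_s,
    noise_sd = noise_sd,
    between_subject_cv = between_subject_cv,
    device_clock_offsets = device_clock_offsets,
    device_clock_drift_ppm = device_clock_drift_ppm,
    artifact_spec = artifact_spec,
    artifact_beat_fraction = artifact_beat_fraction,
    artifact_beat_delay_s = artifact_beat_delay_s,
    baseline_s = baseline_s, post_s = post_s,
    ppg_fs = ppg_fs, ecg_fs = ecg_fs, nirs_fs = nirs_fs,
    bp_fs = bp_fs, tilt_fs = tilt_fs, bp_wave_fs = bp_wave_fs,
    sync = isTRUE(sync),
    nirs_emit_od = isTRUE(nirs_emit_od),
    nirs_wavelengths_nm = nirs_wavelengths_nm,
    nirs_distance_cm = nirs_distance_cm,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "ortho_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_scalar_num(cfg$baseline_sbp, "baseline_sbp", positive = TRUE)
  assert_scalar_num(cfg$baseline_dbp, "baseline_dbp", positive = TRUE)
  assert_scalar_num(cfg$baseline_hr, "baseline_hr", positive = TRUE)
  assert_scalar_num(cfg$time_to_nadir, "time_to_nadir", positive = TRUE)
  assert_scalar_num(cfg$recovery_tau, "recovery_tau", positive = TRUE)
  if (cfg$baseline_dbp >= cfg$baseline_sbp)
    rlang::abort("baseline_dbp must be below baseline_sbp")
  if (cfg$time_to_nadir >= 30)
    rlang::abort("time_to_nadir must be < 30 s")
  if (cfg$time_to_nadir >= cfg$recovery_tau)
    rlang::abort("time_to_nadir must be below recovery_tau for the
                  double-exponential response template")
  if (cfg$ptt_slope > 0)
    rlang::abort("ptt_slope must be <= 0 (PTT shortens as BP rises)")
  for (f in c("ppg_fs", "ecg_fs", "nirs_fs", "bp_fs", "tilt_fs",
              "bp_wave_fs"))
    assert_scalar_num(cfg[[f]], f, positive = TRUE)
  if (cfg$baseline_s < 60)
    rlang::abort("baseline_s must be >= 60 s (baseline statistics window)")
  unknown <- setdiff(cfg$maneuvers, maneuver_table()$maneuver)
  if (length(unknown))
    rlang::abort(sprintf("unknown maneuver(s): %s",
                         paste(unknown, collapse = ", ")))
  # recovery must have settled by 60 s post-onset
  resid <- exp(-(60 - cfg$time_to_nadir) / cfg$recovery_tau)
  if (resid > 0.10)
    rlang::warn(sprintf(
      "recovery_tau %.1f s leaves %.0f%% of the drop unrecovered at 60 s",
      cfg$recovery_tau, 100 * resid))
  invisible(cfg)
}
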