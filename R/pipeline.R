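# Orchestration: sessions -> aligned, onset-marked, quality-gated,
# beat-resolved 25-Hz repeats -> cohort metrics and statistics.

#' Preprocess one session into analysis-ready 25-Hz series
#'
#' Aligns the devices (when a sync channel is present), detects movement
#' onset from the trunk tilt, detects R-peaks and PPG upstrokes, builds the
#' per-beat table with the two-stage PWV series, runs the quality gate, and
#' assembles the onset-aligned 25-Hz 5-s-smoothed signal table used by all
#' downstream metrics.
#'
#' @param session an `ortho_session`.
#' @param baseline_s baseline window, s.
#' @param onset_threshold_deg,onset_hold_s onset-detector settings.
#' @param bp_source `"beats"` (default): 25-Hz SBP/MAP by sample-and-hold
#'   of the per-beat BP events; `"waveform"`: resampled from the continuous
#'   BP waveform channels (identical processing path to the other
#'   waveforms).
#' @return An object of class `ortho_prepared`: fields `sig` (tibble on the
#'   onset-relative 25-Hz grid with smoothed columns `finger_ppg`,
#'   `wrist_ppg` (standardized), `o2hb`, `hhb` (uM), `sbp`, `map` (mmHg),
#'   `ibi` (ms), `pwv` (1/s)), `beats`, `quality`, `discard`, `onset`,
#'   ids and the simulator truth (when present).
#' @export
prepare_repeat <- function(session, baseline_s = 60,
                           onset_threshold_deg = 5, onset_hold_s = 0.5,
                           bp_source = c("beats", "waveform")) {
  bp_source <- match.arg(bp_source)
  stopifnot(inherits(session, "ortho_session"))
  session <- align_session(session)
  ch <- session$channels
  if (!"t0" %in% names(ch)) ch$t0 <- 0
  get_ch <- function(name) {
    j <- which(ch$channel == name)
    if (!length(j)) return(NULL)
    list(x = ch$samples[[j[1]]], fs = ch$fs[j[1]], t0 = ch$t0[j[1]])
  }

  tilt <- get_ch("tilt")
  if (is.null(tilt)) rlang::abort("session has no tilt channel")
  t_tilt <- tilt$t0 + (seq_along(tilt$x) - 1) / tilt$fs
  onset <- detect_onset(t_tilt, tilt$x, onset_threshold_deg, onset_hold_s,
                        baseline_s)

  ecg <- get_ch("ecg")
  if (is.null(ecg)) rlang::abort("session has no ECG channel")
  r_times <- detect_r_peaks(ecg$x, ecg$fs, ecg$t0)

  fp <- get_ch("finger_ppg")
  wp <- get_ch("wrist_ppg")
  fp_bp <- bandpass_ppg(fp$x, fp$fs)
  beats <- build_beat_series(r_times, session$bp_beats, fp_bp, fp$fs,
                             fp$t0)
  wp_up <- if (!is.null(wp))
    detect_ppg_upstrokes(bandpass_ppg(wp$x, wp$fs), wp$fs, r_times, 1.5,
                         wp$t0)
  else NULL

  # ---- quality gate ----
  events <- list(ecg = r_times, bp = session$bp_beats$t)
  sampled <- list()
  # PPG channels are judged by heartbeat gaps when pulses are visible for
  # at least half the beats; a PPG without pulsatile content (e.g. an
  # envelope-only signal) is judged by missing-sample gaps instead.
  add_ppg <- function(name, up, s) {
    if (mean(up$detected) >= 0.5)
      events[[name]] <<- up$upstroke_time[up$detected]
    else
      sampled[[name]] <<- list(t = s$t0 + (seq_along(s$x) - 1) / s$fs,
                               na = is.na(s$x))
  }
  add_ppg("finger_ppg",
          tibble::tibble(upstroke_time = beats$upstroke_time,
                         detected = !is.na(beats$upstroke_time)), fp)
  if (!is.null(wp_up)) add_ppg("wrist_ppg", wp_up, wp)
  for (nm in c("o2hb", "hhb")) {
    s <- get_ch(nm)
    if (!is.null(s))
      sampled[[nm]] <- list(t = s$t0 + (seq_along(s$x) - 1) / s$fs,
                            na = is.na(s$x))
  }
  quality <- assess_quality(events, onset, sampled, baseline_s)

  # ---- 25-Hz onset-aligned table ----
  dur <- min(onset + 180,
             max(t_tilt))
  t25 <- seq(max(0, onset - baseline_s - 5), dur, by = 1 / 25)
  t_rel <- seq(-baseline_s, 180, by = 1 / 25)

  smooth_of <- function(chan, use = c("std", "raw")) {
    use <- match.arg(use)
    s <- get_ch(chan)
    if (is.null(s)) return(rep(NA_real_, length(t_rel)))
    r <- resample_25(s$x, s$fs, s$t0, t_out = t25)
    p <- standardize_and_smooth(r$t, r$value, onset, baseline_s)
    y <- if (use == "std") p$smooth else p$smooth_raw
    approx(t25 - onset, y, xout = t_rel, rule = 2)$y
  }
  hold_smooth <- function(t_ev, v) {
    ok <- !is.na(t_ev) & !is.na(v)
    if (sum(ok) < 2) return(rep(NA_real_, length(t_rel)))
    h <- hold_25(t_ev[ok], v[ok], t25)
    sm <- moving_average(h$value, 125L)
    approx(t25 - onset, sm, xout = t_rel, rule = 2)$y
  }

  sig <- tibble::tibble(
    t = t_rel,
    finger_ppg = smooth_of("finger_ppg", "std"),
    finger_ppg_raw = smooth_of("finger_ppg", "raw"),
    wrist_ppg = smooth_of("wrist_ppg", "std"),
    o2hb = smooth_of("o2hb", "raw"),
    hhb = smooth_of("hhb", "raw"),
    sbp = if (bp_source == "waveform") smooth_of("bp_sbp", "raw")
          else hold_smooth(session$bp_beats$t, session$bp_beats$sbp),
    map = if (bp_source == "waveform") smooth_of("bp_map", "raw")
          else hold_smooth(session$bp_beats$t, session$bp_beats$map),
    ibi = hold_smooth(beats$r_time, beats$ibi_ms),
    pwv = hold_smooth(beats$r_time[beats$flag == "ok"],
                      beats$pwv[beats$flag == "ok"])
  )

  structure(list(
    participant = session$participant,
    maneuver = session$maneuver,
    rep_idx = session$rep_idx,
    onset = onset,
    sig = sig,
    beats = beats,
    quality = quality,
    discard = any(quality$discard),
    truth = session$truth
  ), class = "ortho_prepared")
}

#' @export
print.ortho_prepared <- function(x, ...) {
  cat(sprintf(
    "<ortho_prepared> participant %s, %s, repeat %d: onset %.2f s%s\n",
    x$participant, x$maneuver, x$rep_idx, x$onset,
    if (x$discard) " [DISCARDED]" else ""))
  invisible(x)
}

correlation_signals <- c("finger_ppg", "wrist_ppg", "o2hb", "hhb", "pwv",
                         "sbp")

drop_quantities <- function(prep, window_s = 60, baseline_s = 60) {
  d <- function(col) {
    x <- prep$sig[[col]]
    if (all(is.na(x))) return(NA_real_)
    compute_drop(prep$sig$t, x, 0, window_s, baseline_s)$drop
  }
  list(ibi = d("ibi"), sbp = d("sbp"), map = d("map"), o2hb = d("o2hb"))
}

#' Analyze a cohort of sessions
#'
#' Runs the full analysis over a simulated or loaded cohort: per-repeat
#' preparation and quality gating, per-participant signal-MAP correlations
#' (repeat-averaged), measured- and estimated-BP (leave-one-repeat-out)
#' drop-method BRS/CAR with the cohort 5-SD outlier rule, ICC(A,1)
#' reliability per maneuver, and measured-vs-estimated validity
#' correlations.
#'
#' @param cohort tibble from [simulate_cohort()] (columns `participant`,
#'   `maneuver`, `rep_idx`, `session`), or a list of `ortho_session`s.
#' @param fit_window BP-regression fit window relative to onset, s.
#' @param drop_window_s BRS/CAR drop search window, s.
#' @param bp_source measured-BP source, see [prepare_repeat()].
#' @return list of class `ortho_report`: tibbles `correlations`,
#'   `correlation_summary`, `estimates`, `reliability`, `validity`,
#'   `quality`, and the run `manifest`.
#' @export
analyze_cohort <- function(cohort, fit_window = c(0, 30),
                           drop_window_s = 60,
                           bp_source = c("beats", "waveform")) {
  bp_source <- match.arg(bp_source)
  if (!is.data.frame(cohort)) {
    cohort <- tibble::tibble(
      participant = vapply(cohort, `[[`, 1, "participant"),
      maneuver = vapply(cohort, `[[`, "", "maneuver"),
      rep_idx = vapply(cohort, function(s) as.integer(s$rep_idx), 1L),
      session = cohort)
  }
  failures <- list()
  prepared <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    prepared[[i]] <- tryCatch(
      prepare_repeat(cohort$session[[i]], bp_source = bp_source),
      error = function(e) {
        failures[[length(failures) + 1L]] <<- tibble::tibble(
          participant = cohort$participant[i],
          maneuver = cohort$maneuver[i],
          rep_idx = cohort$rep_idx[i],
          error = conditionMessage(e))
        NULL
      })
  }
  keep <- !vapply(prepared, is.null, TRUE)
  prepared <- prepared[keep]
  meta <- cohort[keep, c("participant", "maneuver", "rep_idx")]

  quality <- dplyr::bind_rows(lapply(prepared, function(p)
    dplyr::mutate(p$quality, participant = p$participant,
                  maneuver = p$maneuver, rep_idx = p$rep_idx,
                  .before = 1)))
  good <- !vapply(prepared, `[[`, TRUE, "discard")

  groups <- split(seq_along(prepared),
                  paste(meta$participant, meta$maneuver, sep = "\r"))

  cors <- list(); est_rows <- list()
  for (g in groups) {
    reps <- prepared[g]
    ok <- good[g]
    pid <- reps[[1]]$participant; man <- reps[[1]]$maneuver
    reps_ok <- reps[ok]
    if (!length(reps_ok)) next
    # ---- signal-MAP correlations (repeat-averaged) ----
    for (sig_name in correlation_signals) {
      df <- dplyr::bind_rows(lapply(reps_ok, function(p)
        tibble::tibble(rep = p$rep_idx, t = p$sig$t,
                       signal = p$sig[[sig_name]], map = p$sig$map)))
      r <- tryCatch(signal_map_correlation(df, onset = 0),
                    error = function(e) NA_real_)
      cors[[length(cors) + 1L]] <- tibble::tibble(
        participant = pid, maneuver = man, signal = sig_name, r = r)
    }
    # ---- measured-BP drops ----
    drops <- lapply(reps_ok, drop_quantities, window_s = drop_window_s)
    # ---- leave-one-repeat-out estimated BP ----
    est_sbp <- est_map <- vector("list", length(reps_ok))
    if (man != "squat_1min" && length(reps_ok) >= 2) {
      mk <- function(p, bpcol) {
        # regression on the raw smoothed finger PPG: the PPG-to-BP map must
        # transfer across repeats, so no per-repeat standardization here
        out <- tibble::tibble(t = p$sig$t, ppg = p$sig$finger_ppg_raw,
                              bp = p$sig[[bpcol]])
        attr(out, "onset") <- 0
        out
      }
      est_sbp <- loro_estimates(lapply(reps_ok, mk, bpcol = "sbp"),
                                fit_window)
      est_map <- loro_estimates(lapply(reps_ok, mk, bpcol = "map"),
                                fit_window)
    }
    for (j in seq_along(reps_ok)) {
      p <- reps_ok[[j]]
      d <- drops[[j]]
      add <- function(quantity, value)
        est_rows[[length(est_rows) + 1L]] <<- tibble::tibble(
          participant = pid, maneuver = man, rep_idx = p$rep_idx,
          quantity = quantity, value = value)
      add("BRS_measured", brs_drop(d$ibi, d$sbp))
      add("CAR_measured", car_drop(d$o2hb, d$map))
      if (!is.null(est_sbp[[j]])) {
        es <- compute_drop(p$sig$t, est_sbp[[j]]$estimate, 0,
                           drop_window_s)$drop
        em <- compute_drop(p$sig$t, est_map[[j]]$estimate, 0,
                           drop_window_s)$drop
        add("BRS_estimated", brs_drop(d$ibi, es))
        add("CAR_estimated", car_drop(d$o2hb, em))
      }
    }
  }
  correlations <- dplyr::bind_rows(cors)
  estimates <- dplyr::bind_rows(est_rows)

  # ---- cohort 5-SD outlier rule, per maneuver x quantity ----
  if (nrow(estimates)) {
    estimates <- estimates |>
      dplyr::group_by(maneuver, quantity) |>
      dplyr::mutate(discarded = discard_outlier_estimates(value)) |>
      dplyr::ungroup()
  } else estimates$discarded <- logical()

  used <- dplyr::filter(estimates, !discarded, is.finite(value))

  # ---- reliability: ICC(A,1) per maneuver x quantity ----
  rel_rows <- list()
  for (key in split(used, paste(used$maneuver, used$quantity, sep = "\r"))) {
    if (!nrow(key)) next
    wide <- tidyr::pivot_wider(key[, c("participant", "rep_idx", "value")],
                               names_from = rep_idx, values_from = value)
    mat <- as.matrix(wide[, -1, drop = FALSE])
    res <- tryCatch(icc_a1(mat), error = function(e) NULL)
    rel_rows[[length(rel_rows) + 1L]] <- tibble::tibble(
      maneuver = key$maneuver[1], quantity = key$quantity[1],
      icc = if (is.null(res)) NA_real_ else res$icc,
      band = if (is.null(res)) NA_character_
             else as.character(res$band),
      n_participants = if (is.null(res)) sum(stats::complete.cases(mat))
                       else res$n,
      n_repeats = ncol(mat))
  }
  reliability <- dplyr::bind_rows(rel_rows)

  # ---- validity: measured vs estimated, repeat-averaged ----
  val_rows <- list()
  for (man in unique(used$maneuver)) {
    for (q in c("BRS", "CAR")) {
      pm <- used |>
        dplyr::filter(maneuver == man,
                      quantity %in% paste0(q, c("_measured",
                                                "_estimated"))) |>
        dplyr::group_by(participant, quantity) |>
        dplyr::summarise(value = mean(value), .groups = "drop") |>
        tidyr::pivot_wider(names_from = quantity, values_from = value)
      mcol <- paste0(q, "_measured"); ecol <- paste0(q, "_estimated")
      r <- if (all(c(mcol, ecol) %in% names(pm)))
        validity_correlation(pm[[mcol]], pm[[ecol]]) else NA_real_
      val_rows[[length(val_rows) + 1L]] <- tibble::tibble(
        maneuver = man, quantity = q, r = r,
        n = if (all(c(mcol, ecol) %in% names(pm)))
          sum(is.finite(pm[[mcol]]) & is.finite(pm[[ecol]])) else 0L)
    }
  }
  validity <- dplyr::bind_rows(val_rows)

  manifest <- list(
    n_sessions = nrow(cohort),
    n_prepared = length(prepared),
    n_failed = length(failures),
    n_quality_discarded = sum(!good),
    discarded_repeats = meta[!good, , drop = FALSE],
    n_estimate_outliers = sum(estimates$discarded %||% FALSE)
  )

  structure(list(
    correlations = correlations,
    correlation_summary = cohort_summary(correlations, r, maneuver,
                                         signal),
    estimates = estimates,
    reliability = reliability,
    validity = validity,
    quality = quality,
    failures = dplyr::bind_rows(failures),
    manifest = manifest
  ), class = "ortho_report")
}

#' @export
print.ortho_report <- function(x, ...) {
  cat(sprintf(
    "<ortho_report> %d sessions (%d discarded), %d estimates (%d outliers)\n",
    x$manifest$n_sessions, x$manifest$n_quality_discarded,
    nrow(x$estimates), x$manifest$n_estimate_outliers))
  cat("tables: correlations, correlation_summary, estimates, reliability,",
      "validity, quality\n")
  invisible(x)
}

#' Run the full simulate-and-analyze pipeline
#'
#' Simulates a cohort from the configuration, analyzes it, and (optionally)
#' writes the result tables as CSV plus a JSON run manifest. Deterministic
#' for a given configuration and seed.
#'
#' @param config an [sim_config()] object.
#' @param out_dir optional output directory for `estimates.csv`,
#'   `correlations.csv`, `reliability.csv`, `validity.csv`, `quality.csv`
#'   and `manifest.json`.
#' @return the [analyze_cohort()] report, invisibly when writing.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cohort <- simulate_cohort(config)
  report <- analyze_cohort(cohort)
  report$manifest$config_hash <- rlang::hash(unclass(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name)
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                       quote = FALSE)
    wr(report$estimates, "estimates.csv")
    wr(report$correlations, "correlations.csv")
    wr(report$reliability, "reliability.csv")
    wr(report$validity, "validity.csv")
    wr(report$quality, "quality.csv")
    man <- report$manifest
    man$discarded_repeats <- as.data.frame(man$discarded_repeats)
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    return(invisible(report))
  }
  report
}
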