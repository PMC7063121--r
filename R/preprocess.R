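# Filtering, resampling, baseline standardization, onset detection and the
# automated signal-quality gate.

# Zero-phase filtering with odd-reflection padding at both ends, which
# suppresses the start/end transients of plain filtfilt.
filtfilt_pad <- function(bf, x, pad_n) {
  n <- length(x)
  p <- min(pad_n, n - 1L)
  if (p < 2L) return(as.numeric(signal::filtfilt(bf, x)))
  left <- 2 * x[1] - x[(p + 1L):2]
  right <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- as.numeric(signal::filtfilt(bf, c(left, x, right)))
  y[(p + 1L):(p + n)]
}

#' Band-pass filter a PPG signal
#'
#' Zero-phase Butterworth band-pass (default 0.05-10 Hz, order 2 per
#' direction, applied forward-backward). Run at the native rate before
#' upstroke detection; removes DC/drift and high-frequency noise while
#' preserving the systolic upstroke.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz; must exceed twice the upper band edge.
#' @param band passband edges, Hz.
#' @param order Butterworth order per direction.
#' @return filtered vector, same length.
#' @export
bandpass_ppg <- function(x, fs, band = c(0.05, 10), order = 2) {
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (fs <= 2 * band[2])
    rlang::abort(sprintf(
      "sampling rate %.1f Hz too low for a %.1f Hz band edge", fs, band[2]))
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  filtfilt_pad(bf, x, round(30 * fs))
}

#' Resample a waveform channel to 25 Hz
#'
#' Zero-phase Butterworth low-pass (anti-alias, cutoff just below the
#' target Nyquist) followed by linear interpolation onto the uniform
#' target grid.
#'
#' @param x numeric vector.
#' @param fs native rate, Hz (>= target).
#' @param t0 time of the first sample, s.
#' @param target target rate, Hz.
#' @param t_out optional explicit output grid (s); defaults to
#'   `seq(t0, by = 1/target)` over the covered span.
#' @return tibble with `t` and `value` at the target rate.
#' @export
resample_25 <- function(x, fs, t0 = 0, target = 25, t_out = NULL) {
  if (!length(x)) rlang::abort("resample_25(): empty input")
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (fs < target)
    rlang::abort("waveform resampling requires a native rate >= target")
  t_in <- t0 + (seq_along(x) - 1) / fs
  if (is.null(t_out))
    t_out <- seq(t0, t_in[length(t_in)], by = 1 / target)
  if (fs > target) {
    bf <- signal::butter(4, (0.45 * target) / (fs / 2), type = "low")
    good <- !is.na(x)
    pad <- round(2 * fs)
    if (all(good)) {
      xf <- filtfilt_pad(bf, x, pad)
    } else {
      # filter contiguous finite stretches; keep NA gaps as missing
      xf <- rep(NA_real_, length(x))
      r <- rle(good)
      ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1) + 1L)
      for (k in which(r$values)) {
        idx <- starts[k]:ends[k]
        xf[idx] <- if (length(idx) > 12 * 3)
          filtfilt_pad(bf, x[idx], pad) else x[idx]
      }
    }
  } else xf <- x
  y <- approx(t_in, xf, xout = t_out, rule = 2)$y
  # propagate missingness: output sample is NA if nearest input is NA
  if (anyNA(xf)) {
    na_near <- approx(t_in, as.numeric(is.na(xf)), xout = t_out, rule = 2)$y
    y[na_near > 0] <- NA_real_
  }
  tibble::tibble(t = t_out, value = y)
}

#' Resample a per-beat event series to 25 Hz by sample-and-hold
#'
#' Previous-value interpolation of per-beat quantities (SBP, DBP, MAP, IBI,
#' PWV) onto the 25-Hz grid; times before the first beat hold the first
#' value.
#'
#' @param t_event event times, s.
#' @param value per-event values.
#' @param t_out output grid, s.
#' @return tibble with `t` and `value`.
#' @export
hold_25 <- function(t_event, value, t_out) {
  ok <- is.finite(t_event) & !is.na(value)
  if (!any(ok)) rlang::abort("hold_25(): no valid events")
  tibble::tibble(t = t_out, value = hold_interp(t_event[ok], value[ok], t_out))
}

#' Baseline standardization and 5-s moving average
#'
#' From a 25-Hz series, computes the baseline-standardized version
#' (subtract the baseline mean, divide by the baseline SD; baseline = the
#' 60 s before movement onset) and 5-s centered moving-average versions of
#' both the raw and the standardized series (shrinking windows at the
#' edges).
#'
#' @param t time vector, s (uniform 25 Hz).
#' @param x values.
#' @param onset movement onset, s.
#' @param baseline_s baseline window length before onset, s.
#' @param ma_s moving-average window, s.
#' @return tibble with columns `t`, `raw`, `std`, `smooth` (5-s MA of the
#'   standardized series) and `smooth_raw` (5-s MA of the raw series);
#'   attributes `baseline_mean`, `baseline_sd`.
#' @export
standardize_and_smooth <- function(t, x, onset, baseline_s = 60, ma_s = 5) {
  fs <- 1 / median(diff(t))
  bl <- t >= onset - baseline_s & t < onset
  if (!any(bl))
    rlang::abort("baseline window lies outside the recording")
  m <- mean(x[bl], na.rm = TRUE)
  s <- sd(x[bl], na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    rlang::abort("degenerate baseline: zero variance")
  std <- (x - m) / s
  k <- 2L * floor(ma_s * fs / 2) + 1L   # 125 samples at 25 Hz
  out <- tibble::tibble(
    t = t, raw = x, std = std,
    smooth = moving_average(std, k),
    smooth_raw = moving_average(x, k)
  )
  attr(out, "baseline_mean") <- m
  attr(out, "baseline_sd") <- s
  out
}

#' Detect movement onset from the trunk-tilt channel
#'
#' Onset is the first time the tilt angle deviates more than
#' `threshold_deg` from its baseline median and stays deviated for at least
#' `hold_s` seconds.
#'
#' @param t time vector, s.
#' @param angle tilt angle, degrees.
#' @param threshold_deg deviation threshold, degrees.
#' @param hold_s minimum hold time, s.
#' @param baseline_s span used for the baseline median, s (from the start
#'   of the recording).
#' @return onset time, s.
#' @export
detect_onset <- function(t, angle, threshold_deg = 5, hold_s = 0.5,
                         baseline_s = 60) {
  if (t[length(t)] - t[1] < baseline_s)
    rlang::abort("tilt recording shorter than the baseline window")
  fs <- 1 / median(diff(t))
  base_med <- median(angle[t <= t[1] + baseline_s], na.rm = TRUE)
  dev <- abs(angle - base_med) > threshold_deg
  dev[is.na(dev)] <- FALSE
  r <- rle(dev)
  ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1) + 1L)
  hit <- which(r$values & r$lengths >= hold_s * fs)
  if (!length(hit))
    rlang::abort("no movement onset found in tilt channel")
  t[starts[hit[1]]]
}

quality_windows <- function(onset, baseline_s = 60) {
  list(baseline = c(onset - baseline_s, onset),
       minute1 = c(onset, onset + 60),
       minute23 = c(onset + 60, onset + 180))
}

max_gap_events <- function(times, win) {
  inside <- times[times >= win[1] & times <= win[2]]
  max(diff(c(win[1], sort(inside), win[2])))
}

max_gap_missing <- function(t, is_na, win) {
  sel <- t >= win[1] & t <= win[2]
  if (!any(sel)) return(0)
  fs <- 1 / median(diff(t))
  longest_true_run_s(is_na[sel], fs)
}

#' Automated signal-quality gate
#'
#' Implements the heartbeat-gap discard rules: a channel (and with it the
#' repeat) is discarded when it shows no heartbeat for more than 10 s
#' during baseline (the 60 s before the movement), more than 10 s in the
#' first minute after movement onset, or more than 20 s in minutes two and
#' three. Sample-valued channels (NIRS, continuous BP) are judged by
#' missing-sample gaps against the same thresholds.
#'
#' @param events named list of beat-time vectors (s) for the pulsatile
#'   channels (e.g. `ecg`, `finger_ppg`, `wrist_ppg`, `bp`).
#' @param onset movement onset, s.
#' @param sampled optional named list of `list(t=, na=)` for channels judged
#'   by missing samples.
#' @param baseline_s baseline window, s.
#' @param thresholds numeric length-3: max tolerated gap (s) in baseline,
#'   minute 1, minutes 2-3.
#' @return tibble with one row per channel: the three window gaps, the
#'   `discard` flag and a human-readable `reason`.
#' @export
assess_quality <- function(events, onset, sampled = NULL, baseline_s = 60,
                           thresholds = c(10, 10, 20)) {
  wins <- quality_windows(onset, baseline_s)
  one <- function(name, gaps) {
    over <- gaps > thresholds
    reason <- if (any(over)) {
      w <- which(over)[1]
      sprintf("%s gap %.1f s > %g s", names(wins)[w], gaps[w],
              thresholds[w])
    } else NA_character_
    tibble::tibble(channel = name, gap_baseline = gaps[1],
                   gap_minute1 = gaps[2], gap_minute23 = gaps[3],
                   discard = any(over), reason = reason)
  }
  rows <- list()
  for (nm in names(events))
    rows[[length(rows) + 1L]] <- one(nm, vapply(
      wins, function(w) max_gap_events(events[[nm]], w), 0))
  for (nm in names(sampled))
    rows[[length(rows) + 1L]] <- one(nm, vapply(
      wins, function(w) max_gap_missing(sampled[[nm]]$t,
                                        sampled[[nm]]$na, w), 0))
  dplyr::bind_rows(rows)
}
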