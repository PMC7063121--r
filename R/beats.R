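# Beat detection, per-beat series assembly and two-stage PWV extraction.
#
# "PWV" here is the reciprocal of the ECG R-peak to PPG-upstroke delay
# (a pulse-arrival-time reciprocal, unit 1/s); no path length is involved.

#' Detect ECG R-peaks
#'
#' Adaptive-threshold peak picking on the 5-30 Hz band-passed ECG with a
#' 250-ms refractory period. A pre-extracted R-peak event series can be
#' passed directly (with `fs = NULL`) and is returned unchanged.
#'
#' @param x ECG samples at the native rate, or event times if `fs` is NULL.
#' @param fs sampling rate, Hz; NULL marks `x` as an event series.
#' @param t0 time of the first sample, s.
#' @param threshold_frac peak acceptance threshold as a fraction of the
#'   95th percentile of positive filtered amplitudes.
#' @return numeric vector of R-peak times, s, strictly increasing.
#' @export
detect_r_peaks <- function(x, fs, t0 = 0, threshold_frac = 0.4) {
  if (is.null(fs)) return(sort(as.numeric(x)))
  if (!length(x)) rlang::abort("empty ECG signal")
  band <- c(5, min(30, 0.45 * fs))
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bf, x))
  ref <- quantile(xf[xf > 0], 0.95, na.rm = TRUE)
  if (!is.finite(ref) || ref <= 0) rlang::abort("no R-peaks detectable")
  thr <- threshold_frac * ref
  n <- length(xf)
  is_peak <- c(FALSE, xf[2:(n - 1)] >= xf[1:(n - 2)] &
                 xf[2:(n - 1)] > xf[3:n], FALSE) & xf > thr
  cand <- which(is_peak)
  if (!length(cand)) rlang::abort("no R-peaks detectable")
  # refractory: greedy by amplitude
  ord <- cand[order(xf[cand], decreasing = TRUE)]
  keep <- logical(n)
  refr <- round(0.25 * fs)
  taken <- rep(FALSE, n + 2L * refr)
  for (i in ord) {
    if (!taken[i + refr]) {
      keep[i] <- TRUE
      lo <- i; hi <- min(n, i + refr) # mark neighborhood
      taken[(i):(i + 2L * refr)] <- TRUE
    }
  }
  idx <- which(keep)
  shift <- vapply(idx, function(i) parabolic_refine(xf, i), 0)
  sort(t0 + (idx - 1 + shift) / fs)
}

# Sub-sample refinement of a local maximum by parabolic interpolation of
# the three samples around it; returns a fractional index shift in
# [-0.5, 0.5].
parabolic_refine <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(0)
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (!is.finite(denom) || denom >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (y[i - 1L] - y[i + 1L]) / denom))
}

# Rolling SD of `x` over a centered window of `k` samples (shrinking at the
# edges), via cumulative sums.
rolling_sd <- function(x, k) {
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n)
  lo <- pmax(1L, i - half); hi <- pmin(n, i + half)
  m <- hi - lo + 1L
  mu <- (cs[hi + 1L] - cs[lo]) / m
  v <- pmax(0, (cs2[hi + 1L] - cs2[lo]) / m - mu^2)
  sqrt(v * m / pmax(1, m - 1))
}

#' Detect PPG upstrokes following each R-peak
#'
#' For each R-peak, the candidate upstroke is the maximum of the PPG first
#' derivative in the window `(r, r + 0.6 s]`; it is accepted when the
#' derivative peak exceeds `threshold_k` standard deviations of the PPG
#' first derivative over the centered surrounding 5 s. `threshold_k = 3`
#' gives the high-specificity series, `1.5` the high-sensitivity series.
#'
#' @param ppg band-passed PPG at the native rate (see [bandpass_ppg()]).
#' @param fs sampling rate, Hz.
#' @param r_times R-peak times, s.
#' @param threshold_k acceptance threshold in derivative-SD units.
#' @param t0 time of the first PPG sample, s.
#' @param window_s search window after each R-peak, s.
#' @param sd_window_s span of the surrounding-SD window, s.
#' @return tibble with `r_time`, `upstroke_time` (NA when no candidate
#'   passes) and `detected`.
#' @export
detect_ppg_upstrokes <- function(ppg, fs, r_times, threshold_k = 1.5,
                                 t0 = 0, window_s = 0.6, sd_window_s = 5) {
  d <- diff(ppg)
  d[is.na(d)] <- 0
  sd5 <- rolling_sd(d, 2L * floor(sd_window_s * fs / 2) + 1L)
  # floor the local SD at 10% of the whole-record derivative SD: inside a
  # flatlined dropout the surrounding SD collapses and a purely relative
  # threshold would accept numerical ripple as an upstroke
  sd5 <- pmax(sd5, 0.1 * sd(d))
  up <- rep(NA_real_, length(r_times))
  for (j in seq_along(r_times)) {
    i0 <- floor((r_times[j] - t0) * fs) + 2L
    i1 <- min(length(d), floor((r_times[j] + window_s - t0) * fs) + 1L)
    if (i0 > i1 || i0 < 1L) next
    w <- i0:i1
    i_star <- w[which.max(d[w])]
    if (d[i_star] > threshold_k * sd5[i_star])
      up[j] <- t0 + (i_star - 1 + parabolic_refine(d, i_star)) / fs
  }
  tibble::tibble(r_time = r_times, upstroke_time = up,
                 detected = !is.na(up))
}

#' Per-beat PWV from R-peak/upstroke pairs
#'
#' `pwv = 1 / (upstroke - r)`, unit 1/s. Non-positive delays are flagged
#' invalid; absent upstrokes propagate as NA with flag `no_upstroke`.
#'
#' @param r_times,upstroke_times paired times, s.
#' @return tibble with `r_time`, `delay_s`, `pwv` and `flag`
#'   (`ok` / `no_upstroke` / `invalid_delay`).
#' @export
compute_pwv <- function(r_times, upstroke_times) {
  delay <- upstroke_times - r_times
  flag <- dplyr::case_when(
    is.na(delay) ~ "no_upstroke",
    delay <= 0 ~ "invalid_delay",
    TRUE ~ "ok"
  )
  pwv <- ifelse(flag == "ok", 1 / delay, NA_real_)
  tibble::tibble(r_time = r_times, delay_s = delay, pwv = pwv, flag = flag)
}

#' Merge the two-stage PWV series
#'
#' Values in the high-sensitivity (k = 1.5) series outside
#' `[mean - 3*SD, mean + 5*SD]` of the high-specificity (k = 3) series are
#' discarded; the kept high-sensitivity values form the final series. With
#' an empty high-specificity series the high-sensitivity series is kept
#' unfiltered, with a warning.
#'
#' @param pwv_hispec,pwv_hisens per-beat tibbles from [compute_pwv()] over
#'   the same repeat (matched by row/beat).
#' @return `pwv_hisens` with updated `pwv` and `flag`
#'   (`discarded_pwv` for values outside the band).
#' @export
merge_two_stage <- function(pwv_hispec, pwv_hisens) {
  ref <- pwv_hispec$pwv[pwv_hispec$flag == "ok"]
  out <- pwv_hisens
  if (!length(ref)) {
    rlang::warn("empty high-specificity PWV series; keeping the
                 high-sensitivity series unfiltered")
    return(out)
  }
  m <- mean(ref); s <- sd(ref)
  if (!is.finite(s)) s <- 0
  bad <- out$flag == "ok" &
    (out$pwv < m - 3 * s | out$pwv > m + 5 * s)
  out$flag[bad] <- "discarded_pwv"
  out$pwv[bad] <- NA_real_
  out
}

# Match each R-peak to the nearest BP beat event (within tol) and return the
# per-beat value.
match_nearest <- function(r_times, ev_times, ev_values, tol = 0.4) {
  if (!length(ev_times)) return(rep(NA_real_, length(r_times)))
  idx <- findInterval(r_times, ev_times)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(ev_times))
  d_lo <- abs(r_times - ev_times[lo])
  d_hi <- abs(r_times - ev_times[hi])
  pick <- ifelse(d_hi < d_lo, hi, lo)
  val <- ev_values[pick]
  val[pmin(d_lo, d_hi) > tol] <- NA_real_
  val
}

#' Build the per-beat series for one repeat
#'
#' Combines detected R-peaks, the Finapres-style per-beat BP events and the
#' two-stage PPG upstroke detection into one beat table: IBI (ms), per-beat
#' SBP/DBP/MAP (nearest BP event), the final PWV series and its flags.
#'
#' @param r_times R-peak times, s.
#' @param bp_beats tibble with `t`, `sbp`, `dbp`, `map`.
#' @param ppg_bandpassed band-passed finger PPG at native rate.
#' @param fs PPG sampling rate, Hz.
#' @param t0 PPG start time, s.
#' @return tibble: `r_time`, `ibi_ms`, `sbp`, `dbp`, `map`,
#'   `upstroke_time`, `pwv`, `flag`.
#' @export
build_beat_series <- function(r_times, bp_beats, ppg_bandpassed, fs,
                              t0 = 0) {
  hispec <- detect_ppg_upstrokes(ppg_bandpassed, fs, r_times, 3.0, t0)
  hisens <- detect_ppg_upstrokes(ppg_bandpassed, fs, r_times, 1.5, t0)
  merged <- merge_two_stage(compute_pwv(r_times, hispec$upstroke_time),
                            compute_pwv(r_times, hisens$upstroke_time))
  tibble::tibble(
    r_time = r_times,
    ibi_ms = c(NA_real_, diff(r_times)) * 1000,
    sbp = match_nearest(r_times, bp_beats$t, bp_beats$sbp),
    dbp = match_nearest(r_times, bp_beats$t, bp_beats$dbp),
    map = match_nearest(r_times, bp_beats$t, bp_beats$map),
    upstroke_time = hisens$upstroke_time,
    pwv = merged$pwv,
    flag = merged$flag
  )
}
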