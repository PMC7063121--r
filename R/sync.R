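# Shared pulse-train reference channel: encoding, decoding, alignment.
#
# Each minute boundary m carries a frame of 16 pulse slots (200 ms slot
# period). Slot k holds a wide pulse (120 ms) if bit k of m is set, else a
# narrow pulse (40 ms), least-significant bit first. Amplitude 1 over a 0
# baseline. The widths are chosen so that one-sample quantization jitter at
# a 50-Hz device can never cross the 80-ms wide/narrow decision boundary.
# The codec is a self-consistent pair: any device that records the same
# analog line can be re-clocked by decoding it.

SYNC_SLOT_S <- 0.2
SYNC_WIDE_S <- 0.12
SYNC_NARROW_S <- 0.04
SYNC_FRAME_SLOTS <- 16L

# Vectorized reference waveform at arbitrary (reference-clock) times.
sync_wave <- function(t) {
  v <- numeric(length(t))
  pos <- t >= 0
  tt <- t[pos]
  m <- floor(tt / 60)
  tau0 <- tt - 60 * m
  in_frame <- tau0 < SYNC_SLOT_S * SYNC_FRAME_SLOTS
  k <- pmin(floor(tau0 / SYNC_SLOT_S), SYNC_FRAME_SLOTS - 1)
  tau <- tau0 - k * SYNC_SLOT_S
  bit <- bitwAnd(as.integer(m %% 65536), bitwShiftL(1L, as.integer(k))) > 0
  width <- ifelse(bit, SYNC_WIDE_S, SYNC_NARROW_S)
  v[pos] <- as.numeric(in_frame & tau < width)
  v
}

#' Encode the shared pulse-train reference signal
#'
#' @param n_minutes number of minutes to encode (frames at minutes
#'   `0 .. n_minutes - 1`); must be below 2^16.
#' @param sampling_rate sampling rate, Hz.
#' @return numeric vector of `n_minutes * 60 * sampling_rate` samples.
#' @export
#' @examples
#' x <- encode_reference_signal(2, 100)
#' sum(x > 0.5) / 100  # total pulse time, s
encode_reference_signal <- function(n_minutes, sampling_rate) {
  assert_scalar_num(n_minutes, "n_minutes", positive = TRUE)
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  if (n_minutes > 65535)
    rlang::abort("n_minutes exceeds the 16-bit frame capacity (2^16 - 1)")
  n <- round(n_minutes * 60 * sampling_rate)
  sync_wave((seq_len(n) - 1) / sampling_rate)
}

#' Decode a recorded reference signal into sync markers
#'
#' Thresholds the signal at 0.5, groups pulses into 16-slot frames (slot
#' starts 200 ms apart, within a 50-ms tolerance) and reads the pulse-width
#' code. Frames with a broken slot pattern are skipped and counted in the
#' `n_corrupt` attribute.
#'
#' @param samples numeric vector (device clock).
#' @param sampling_rate Hz.
#' @param t0 device-clock time of the first sample, s.
#' @return tibble with `device_time` (frame start on the device clock, s)
#'   and `minute` (decoded minute index); attribute `n_corrupt`.
#' @export
decode_reference_signal <- function(samples, sampling_rate, t0 = 0) {
  on <- !is.na(samples) & samples > 0.5
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts_i <- c(1L, utils::head(ends, -1L) + 1L)
  pi <- which(r$values)
  if (!length(pi)) rlang::abort("no decodable sync frame found")
  p_start <- t0 + (starts_i[pi] - 1L) / sampling_rate
  p_width <- r$lengths[pi] / sampling_rate
  np <- length(p_start)
  out_t <- numeric(0); out_m <- integer(0); n_corrupt <- 0L
  i <- 1L
  while (i + SYNC_FRAME_SLOTS - 1L <= np) {
    idx <- i:(i + SYNC_FRAME_SLOTS - 1L)
    d <- diff(p_start[idx])
    if (all(abs(d - SYNC_SLOT_S) < 0.05)) {
      wide <- p_width[idx] > (SYNC_WIDE_S + SYNC_NARROW_S) / 2
      minute <- sum(as.integer(wide) * 2^(0:(SYNC_FRAME_SLOTS - 1L)))
      out_t <- c(out_t, p_start[i])
      out_m <- c(out_m, as.integer(minute))
      i <- i + SYNC_FRAME_SLOTS
    } else {
      # broken slot pattern: skip to the pulse after the first long gap
      brk <- which(d > SYNC_SLOT_S * 1.5)[1]
      i <- if (is.na(brk)) i + SYNC_FRAME_SLOTS else i + brk
      n_corrupt <- n_corrupt + 1L
    }
  }
  if (!length(out_t)) rlang::abort("no decodable sync frame found")
  out <- tibble::tibble(device_time = out_t, minute = out_m)
  attr(out, "n_corrupt") <- n_corrupt
  out
}

#' Align all devices of a session to the reference clock
#'
#' Decodes each device's recording of the shared pulse-train channel and
#' fits, per device, a least-squares line of marker device-time on
#' `60 * minute` (offset plus optional linear drift). Channel start times
#' and effective rates are then re-expressed on the reference clock, as is
#' the per-beat BP event table. Sessions whose sidecar declares the devices
#' pre-aligned pass through unchanged.
#'
#' @param session an `ortho_session`.
#' @param drift logical; fit a linear clock-drift term (default TRUE). With
#'   `FALSE` the slope is fixed at 1 and only the offset is estimated.
#' @return the session with re-timed channels; `$alignment` holds a tibble
#'   of per-device offset, slope and residual SD.
#' @export
align_session <- function(session, drift = TRUE) {
  stopifnot(inherits(session, "ortho_session"))
  ch <- session$channels
  if (!"t0" %in% names(ch)) ch$t0 <- 0
  already <- !is.null(session$alignment) ||
    (isTRUE(session$pre_aligned) && !"sync" %in% ch$channel)
  if (already) {
    session$channels <- ch
    return(session)
  }
  sync_rows <- which(ch$channel == "sync")
  if (!length(sync_rows))
    rlang::abort("session is not pre-aligned and has no sync channel")
  fits <- lapply(sync_rows, function(j) {
    mk <- decode_reference_signal(ch$samples[[j]], ch$fs[j], ch$t0[j])
    if (nrow(mk) < 2)
      rlang::abort(sprintf(
        "device '%s': fewer than 2 sync markers decodable", ch$device[j]))
    if (drift) {
      fit <- lm(device_time ~ I(60 * minute), data = mk)
      beta <- coef(fit)
      res <- sd(stats::residuals(fit))
    } else {
      beta <- c(mean(mk$device_time - 60 * mk$minute), 1)
      res <- sd(mk$device_time - 60 * mk$minute - beta[1])
    }
    tibble::tibble(device = ch$device[j], offset = beta[[1]],
                   slope = beta[[2]], residual_sd = res %||% 0)
  })
  fits <- dplyr::bind_rows(fits)
  for (i in seq_len(nrow(ch))) {
    f <- fits[fits$device == ch$device[i], ]
    if (nrow(f) != 1) next
    # device time t = offset + slope * t_ref  =>  t_ref = (t - offset)/slope
    ch$t0[i] <- (ch$t0[i] - f$offset) / f$slope
    ch$fs[i] <- ch$fs[i] * f$slope
  }
  session$channels <- ch
  f <- fits[fits$device == "finapres", ]
  if (nrow(f) == 1 && !is.null(session$bp_beats))
    session$bp_beats$t <- (session$bp_beats$t - f$offset) / f$slope
  session$alignment <- fits
  session$pre_aligned <- TRUE
  session
}
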