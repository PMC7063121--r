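# Sequence-method baroreflex sensitivity and the baroreflex effectiveness
# index (BEI) on resting beat series.

#' Detect spontaneous SBP ramps
#'
#' Maximal runs of at least `min_len` consecutive beats whose SBP changes
#' monotonically by at least `sbp_threshold` mmHg per beat, in either
#' direction.
#'
#' @param sbp per-beat SBP, mmHg.
#' @param sbp_threshold minimum per-beat change, mmHg.
#' @param min_len minimum ramp length, beats.
#' @return tibble with `start`, `end` (beat indices, inclusive), `length`
#'   and `direction` (`"up"`/`"down"`).
#' @export
#' @examples
#' detect_ramps(c(120, 121.5, 123, 124.5, 120))
detect_ramps <- function(sbp, sbp_threshold = 1, min_len = 3) {
  n <- length(sbp)
  out <- list()
  if (n < min_len) return(empty_ramps())
  d <- diff(sbp)
  dir <- ifelse(d >= sbp_threshold, 1L, ifelse(d <= -sbp_threshold, -1L, 0L))
  r <- rle(dir)
  ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1) + 1L)
  for (k in seq_along(r$values)) {
    if (r$values[k] == 0L) next
    len_beats <- r$lengths[k] + 1L   # run of diffs -> beats
    if (len_beats < min_len) next
    out[[length(out) + 1L]] <- tibble::tibble(
      start = starts[k], end = ends[k] + 1L, length = len_beats,
      direction = if (r$values[k] > 0) "up" else "down")
  }
  if (!length(out)) return(empty_ramps())
  dplyr::bind_rows(out)
}

empty_ramps <- function() {
  tibble::tibble(start = integer(), end = integer(), length = integer(),
                 direction = character())
}

#' Sequence-method BRS
#'
#' For each SBP ramp the IBI segment shifted by `lag` beats qualifies as a
#' baroreflex sequence when every per-beat IBI change is at least
#' `ibi_threshold` ms in the same direction as the ramp and the SBP-IBI
#' regression correlation is at least `r_min`. BRS is the mean regression
#' slope (ms/mmHg) over the qualifying sequences. Thresholds and lag follow
#' the conventional sequence-method criteria and are configurable.
#'
#' @param beats tibble with per-beat `sbp` (mmHg) and `ibi_ms`.
#' @param ramps tibble from [detect_ramps()]; computed if NULL.
#' @param lag IBI shift in beats (0-2).
#' @param sbp_threshold,min_len ramp criteria (used when `ramps` is NULL).
#' @param ibi_threshold minimum concordant per-beat IBI change, ms.
#' @param r_min minimum SBP-IBI correlation.
#' @return list with `brs` (mean slope, NA when no sequence qualifies),
#'   `bei` (see [bei()]), `n_ramps`, `n_sequences` and the per-sequence
#'   tibble `sequences` (`start`, `slope`, `r`).
#' @export
sequence_brs <- function(beats, ramps = NULL, lag = 1,
                         sbp_threshold = 1, min_len = 3,
                         ibi_threshold = 1, r_min = 0.8) {
  stopifnot(lag %in% 0:2)
  if (is.null(ramps))
    ramps <- detect_ramps(beats$sbp, sbp_threshold, min_len)
  n <- nrow(beats)
  seqs <- list()
  qualifies <- rep(FALSE, nrow(ramps))
  for (k in seq_len(nrow(ramps))) {
    idx <- ramps$start[k]:ramps$end[k]
    if (max(idx) + lag > n) next
    ibi_seg <- beats$ibi_ms[idx + lag]
    if (anyNA(ibi_seg)) next
    d_ibi <- diff(ibi_seg)
    sign_need <- if (ramps$direction[k] == "up") 1 else -1
    if (!all(sign_need * d_ibi >= ibi_threshold)) next
    sbp_seg <- beats$sbp[idx]
    fit <- lm(ibi_seg ~ sbp_seg)
    r <- stats::cor(sbp_seg, ibi_seg)
    if (!is.finite(r) || abs(r) < r_min) next
    qualifies[k] <- TRUE
    seqs[[length(seqs) + 1L]] <- tibble::tibble(
      start = ramps$start[k], slope = unname(coef(fit)[2]), r = r)
  }
  sequences <- if (length(seqs)) dplyr::bind_rows(seqs)
    else tibble::tibble(start = integer(), slope = numeric(), r = numeric())
  brs <- if (nrow(sequences)) mean(sequences$slope) else NA_real_
  list(brs = brs,
       bei = bei(nrow(ramps), sum(qualifies)),
       n_ramps = nrow(ramps),
       n_sequences = nrow(sequences),
       sequences = sequences)
}

#' Baroreflex effectiveness index
#'
#' Fraction of SBP ramps accompanied by at least one qualifying baroreflex
#' sequence; in `[0, 1]`, NA when there are no ramps.
#'
#' @param n_ramps number of SBP ramps.
#' @param n_effective number of ramps with a qualifying sequence.
#' @return BEI.
#' @export
bei <- function(n_ramps, n_effective) {
  if (n_ramps < 1) return(NA_real_)
  n_effective / n_ramps
}
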