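# Per-repeat orthostatic metrics: signal-MAP correlation, drop
# measurements, drop-method BRS and CAR, cohort outlier discarding and
# median/IQR summaries.

#' Signal-MAP correlation over the first 30 s after postural change
#'
#' Signals are first averaged pointwise across repeats (on the shared
#' onset-aligned 25-Hz grid), then the Pearson correlation between the
#' averaged signal and averaged MAP is computed over `(onset,
#' onset + window_s]`.
#'
#' @param df tibble with columns `rep` (repeat id), `t` (s), `signal`
#'   (5-s smoothed, standardized for unit-free channels) and `map` (5-s
#'   smoothed measured MAP).
#' @param onset movement onset, s.
#' @param window_s correlation window length, s.
#' @return Pearson r.
#' @export
signal_map_correlation <- function(df, onset, window_s = 30) {
  avg <- df |>
    dplyr::group_by(t) |>
    dplyr::summarise(signal = mean(signal), map = mean(map),
                     .groups = "drop") |>
    dplyr::filter(t > onset, t <= onset + window_s)
  if (nrow(avg) < 3 || sd(avg$signal, na.rm = TRUE) == 0 ||
      sd(avg$map, na.rm = TRUE) == 0)
    rlang::abort("degenerate input for signal-MAP correlation")
  stats::cor(avg$signal, avg$map, use = "complete.obs")
}

#' Baseline-to-nadir drop of a filtered signal
#'
#' Baseline is the mean of the 5-s-smoothed signal over the 60 s before
#' onset; the nadir is the minimum over `(onset, onset + window_s]`;
#' `drop = baseline - nadir` (negative when the signal rose).
#'
#' @param t,x 25-Hz time grid (s) and 5-s-smoothed values.
#' @param onset movement onset, s.
#' @param window_s search window after onset, s (default 60: within 1 min
#'   after postural change).
#' @param baseline_s baseline span before onset, s.
#' @return one-row tibble: `baseline_value`, `nadir_value`, `nadir_time`
#'   (s after onset), `drop`.
#' @export
compute_drop <- function(t, x, onset, window_s = 60, baseline_s = 60) {
  bl <- t >= onset - baseline_s & t < onset
  po <- t > onset & t <= onset + window_s
  dt <- median(diff(t))
  if (!any(bl) || !any(po) || t[1] > onset - baseline_s + dt ||
      t[length(t)] < onset + window_s - dt)
    rlang::abort("signal does not cover the baseline/search windows")
  baseline <- mean(x[bl], na.rm = TRUE)
  xp <- x[po]; tp <- t[po]
  i <- which.min(xp)
  tibble::tibble(baseline_value = baseline, nadir_value = xp[i],
                 nadir_time = tp[i] - onset, drop = baseline - xp[i])
}

#' Drop-method BRS and CAR
#'
#' `brs_drop()`: inter-beat-interval drop divided by SBP drop within 1 min
#' after postural change, ms/mmHg. `car_drop()`: O2Hb drop divided by MAP
#' drop, uM/mmHg. Undefined (NA) when the denominator drop does not exceed
#' `eps`.
#'
#' @param ibi_drop,o2hb_drop numerator drops (ms, uM).
#' @param sbp_drop,map_drop denominator drops, mmHg.
#' @param eps minimum denominator drop, mmHg.
#' @return ratio, or NA when undefined.
#' @export
brs_drop <- function(ibi_drop, sbp_drop, eps = 1) {
  ifelse(is.finite(sbp_drop) & sbp_drop > eps, ibi_drop / sbp_drop,
         NA_real_)
}

#' @rdname brs_drop
#' @export
car_drop <- function(o2hb_drop, map_drop, eps = 1) {
  ifelse(is.finite(map_drop) & map_drop > eps, o2hb_drop / map_drop,
         NA_real_)
}

#' Leave-one-out 5-SD outlier rule for BRS/CAR estimates
#'
#' A value is discarded when it deviates from the mean of the *other*
#' values of the same postural change by more than five times their
#' standard deviation (single pass, leave-one-out). With fewer than three
#' values the rule is inapplicable and nothing is discarded.
#'
#' @param values numeric vector (one maneuver and quantity; NAs allowed and
#'   never flagged).
#' @return logical vector, TRUE = discard.
#' @export
#' @examples
#' discard_outlier_estimates(c(10, 10.5, 9.8, 60))
discard_outlier_estimates <- function(values) {
  flag <- rep(FALSE, length(values))
  ok <- which(is.finite(values))
  if (length(ok) < 3) return(flag)
  for (i in ok) {
    others <- values[setdiff(ok, i)]
    s <- sd(others)
    if (is.finite(s) && abs(values[i] - mean(others)) > 5 * s)
      flag[i] <- TRUE
  }
  flag
}

#' Median and IQR cohort summary
#'
#' Median and linear-interpolation quartiles per group, the summary used
#' for cohort bar-and-error displays.
#'
#' @param df tibble of per-participant values.
#' @param value column to summarise (tidy-eval).
#' @param ... grouping columns (tidy-eval).
#' @return tibble with `median`, `q1`, `q3`, `n` per group.
#' @export
cohort_summary <- function(df, value, ...) {
  df |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      median = median({{ value }}, na.rm = TRUE),
      q1 = quantile({{ value }}, 0.25, na.rm = TRUE, names = FALSE),
      q3 = quantile({{ value }}, 0.75, na.rm = TRUE, names = FALSE),
      n = sum(is.finite({{ value }})),
      .groups = "drop")
}
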