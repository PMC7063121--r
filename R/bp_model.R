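# PPG-based blood-pressure estimation: per participant, per maneuver,
# leave-one-repeat-out ordinary least squares of BP on the 5-s-smoothed
# standardized finger-PPG signal, fitted over 0-30 s after movement onset:
#   BP = beta0 + beta1 * PPG

#' Fit a linear PPG-to-BP model
#'
#' Pooled OLS over the concatenated training samples of all training
#' repeats, restricted to the fit window after movement onset.
#'
#' @param training tibble with columns `ppg` and `bp` (already windowed and
#'   smoothed), one row per 25-Hz sample, any number of repeats
#'   concatenated.
#' @param target `"SBP"` or `"MAP"` (bookkeeping only).
#' @param training_repeats ids of the repeats that contributed.
#' @return an object of class `ortho_bp_model` with fields `beta0`,
#'   `beta1`, `target`, `n`, `r_squared`, `training_repeats`.
#' @export
#' @examples
#' m <- fit_bp_model(tibble::tibble(ppg = 1:10, bp = 5 + 2 * (1:10)), "SBP")
#' c(m$beta0, m$beta1)
fit_bp_model <- function(training, target = c("SBP", "MAP"),
                         training_repeats = integer()) {
  target <- match.arg(target)
  ok <- is.finite(training$ppg) & is.finite(training$bp)
  x <- training$ppg[ok]; y <- training$bp[ok]
  if (length(x) < 3) rlang::abort("too few training samples")
  if (sd(x) == 0) rlang::abort("zero PPG variance in training window")
  fit <- lm(y ~ x)
  b <- coef(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot
        else NA_real_
  structure(
    list(beta0 = unname(b[1]), beta1 = unname(b[2]), target = target,
         n = length(x), r_squared = r2,
         training_repeats = training_repeats),
    class = "ortho_bp_model")
}

#' Estimate BP from PPG with a fitted model
#'
#' @param model an `ortho_bp_model`.
#' @param ppg numeric vector (smoothed standardized finger PPG).
#' @return estimated BP, mmHg.
#' @export
estimate_bp <- function(model, ppg) {
  stopifnot(inherits(model, "ortho_bp_model"))
  model$beta0 + model$beta1 * ppg
}

#' @export
print.ortho_bp_model <- function(x, ...) {
  cat(sprintf("<ortho_bp_model> %s = %.3f + %.3f * PPG  (n=%d, R2=%.3f)\n",
              x$target, x$beta0, x$beta1, x$n, x$r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ortho_bp_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "ppg"),
                 estimate = c(x$beta0, x$beta1))
}

#' @export
glance.ortho_bp_model <- function(x, ...) {
  tibble::tibble(target = x$target, r.squared = x$r_squared, nobs = x$n,
                 n_training_repeats = length(x$training_repeats))
}

#' Leave-one-repeat-out BP estimates
#'
#' For each repeat, fits the PPG-to-BP model on the other quality-passing
#' repeats of the same participant and maneuver and applies it to the
#' held-out repeat. Squat repeats and single-repeat sessions yield no
#' estimate (flagged unavailable).
#'
#' @param repeats list of per-repeat tibbles, each with columns `t`, `ppg`
#'   (smoothed standardized finger PPG), `bp` (smoothed measured BP) and an
#'   `onset` attribute (or list element `onset`).
#' @param fit_window numeric length-2, fit window relative to onset, s.
#' @return list with one element per repeat: `list(model, estimate)` where
#'   `estimate` is the estimated-BP series over the repeat's full grid, or
#'   `NULL` when unavailable.
#' @export
loro_estimates <- function(repeats, fit_window = c(0, 30)) {
  n <- length(repeats)
  out <- vector("list", n)
  if (n < 2) return(out)
  win_df <- function(rr) {
    on <- attr(rr, "onset") %||% rr$onset[1]
    sel <- rr$t > on + fit_window[1] & rr$t <= on + fit_window[2]
    tibble::tibble(ppg = rr$ppg[sel], bp = rr$bp[sel])
  }
  for (r in seq_len(n)) {
    train_ids <- setdiff(seq_len(n), r)
    training <- dplyr::bind_rows(lapply(repeats[train_ids], win_df))
    model <- fit_bp_model(training, "SBP", training_repeats = train_ids)
    out[[r]] <- list(model = model,
                     estimate = estimate_bp(model, repeats[[r]]$ppg))
  }
  out
}
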