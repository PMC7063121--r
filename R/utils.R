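# Internal numeric helpers shared across modules.

#' @importFrom rlang abort warn %||%
#' @importFrom stats approx coef lm median quantile rnorm runif sd setNames
NULL

#' Centered moving average with shrinking edge windows
#'
#' Boxcar mean of width `k` samples; near the edges the window shrinks so the
#' first and last samples average over roughly half a window. Linear-phase:
#' a linear ramp maps to itself in the interior.
#'
#' @param x numeric vector.
#' @param k odd window length in samples.
#' @return numeric vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Previous-value (sample-and-hold) interpolation of an event series onto a
# time grid; times before the first event take the first value.
hold_interp <- function(t_event, value, t_grid) {
  if (length(t_event) == 0L) abort("hold_interp(): empty event series")
  if (length(t_event) == 1L) return(rep(value, length(t_grid)))
  approx(t_event, value, xout = t_grid, method = "constant",
         f = 0, rule = 2)$y
}

# Deterministic child seed from a master seed and a string key, kept within
# the 32-bit signed range. Enables one RNG stream per channel/repeat.
derive_seed <- function(master, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 1000000007
  as.integer((as.numeric(master) * 2654435 + h) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Longest run (seconds) of a logical vector being TRUE, on a uniform grid.
longest_true_run_s <- function(flag, fs) {
  if (!any(flag)) return(0)
  r <- rle(flag)
  max(r$lengths[r$values]) / fs
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a finite numeric scalar", name))
  if (positive && x <= 0)
    abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}
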