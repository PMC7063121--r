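# Reliability and validity statistics: two-way absolute-agreement
# single-measure intraclass correlation, qualitative banding, measured-vs-
# estimated validity correlation and the cross-measure correlation matrix.

#' Two-way absolute-agreement single-measure ICC
#'
#' ICC(A,1): from the two-way ANOVA mean squares of a participants-by-
#' repeats matrix,
#' `ICC = (MSR - MSE) / (MSR + (k-1)*MSE + k/n * (MSC - MSE))`
#' with `n` participants (rows) and `k` repeats (columns). Rows containing
#' missing repeats are dropped (complete-case).
#'
#' @param mat numeric matrix, participants x repeats.
#' @return object of class `ortho_icc`: `icc`, `band`, the mean squares,
#'   `n`, `k`.
#' @export
#' @examples
#' m <- cbind(1:6, 1:6, 1:6)
#' icc_a1(m)$icc   # exact agreement -> 1
icc_a1 <- function(mat) {
  mat <- as.matrix(mat)
  cc <- stats::complete.cases(mat)
  mat <- mat[cc, , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2)
    rlang::abort("ICC needs at least 2 participants with 2 repeats each")
  g <- mean(mat)
  rm_ <- rowMeans(mat); cm <- colMeans(mat)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm - g)^2)
  sse <- sum((mat - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + g)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom <= 0 || (msr == 0 && mse == 0))
    rlang::abort("degenerate matrix: no variance")
  icc <- (msr - mse) / denom
  structure(list(icc = icc, band = icc_band(icc), msr = msr, msc = msc,
                 mse = mse, n = n, k = k),
            class = "ortho_icc")
}

#' @export
print.ortho_icc <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (%s), n = %d participants x %d repeats\n",
              x$icc, x$band, x$n, x$k))
  invisible(x)
}

#' @export
tidy.ortho_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, band = x$band, msr = x$msr, msc = x$msc,
                 mse = x$mse, n = x$n, k = x$k)
}

#' Qualitative ICC band
#'
#' Half-open, lower-inclusive bins: below 0.40 poor, 0.40-0.59 fair,
#' 0.60-0.74 good, 0.75 and above excellent; negative values are poor.
#'
#' @param icc numeric.
#' @return factor with levels poor/fair/good/excellent.
#' @export
#' @examples
#' icc_band(c(0.39, 0.40, 0.60, 0.75))
icc_band <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.40, 0.60, 0.75, Inf), right = FALSE,
      labels = c("poor", "fair", "good", "excellent"))
}

#' Validity correlation between measured- and estimated-BP estimates
#'
#' Pearson correlation over participants between BRS (or CAR) values based
#' on measured BP and on PPG-estimated BP, after averaging each
#' participant's non-discarded repeats. Undefined with fewer than 3
#' complete pairs.
#'
#' @param measured,estimated numeric vectors, one entry per participant
#'   (repeat-averaged).
#' @return Pearson r, or NA.
#' @export
validity_correlation <- function(measured, estimated) {
  ok <- is.finite(measured) & is.finite(estimated)
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(measured[ok], estimated[ok])
}

#' Pairwise correlation matrix across baroreflex measures
#'
#' Pearson correlations between each pair of per-participant measure
#' vectors over their common participants; cells with fewer than 3 common
#' participants are left absent (NA).
#'
#' @param df tibble with one row per participant and one column per
#'   measure (plus an optional `participant` column, ignored).
#' @return symmetric correlation matrix with measure names.
#' @export
cross_measure_matrix <- function(df) {
  df <- dplyr::select(df, -dplyr::any_of("participant"))
  m <- as.matrix(df)
  p <- ncol(m)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    ok <- is.finite(m[, i]) & is.finite(m[, j])
    if (sum(ok) >= 3) {
      out[i, j] <- if (i == j) 1 else stats::cor(m[ok, i], m[ok, j])
    } else if (i == j && sum(ok) >= 1) out[i, j] <- 1
  }
  out
}
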