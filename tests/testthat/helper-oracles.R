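# Independent oracles used by both the unit and the acceptance suites.

# ICC(A,1) from stats::aov two-way mean squares.
icc_a1_aov_oracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  df <- data.frame(y = as.vector(mat),
                   subj = factor(rep(seq_len(n), k)),
                   rep = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rep, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# Exhaustive SBP-ramp scanner (maximal monotone runs).
brute_force_ramps <- function(sbp, thr = 1, min_len = 3) {
  n <- length(sbp)
  found <- list()
  for (i in seq_len(n - 1)) {
    for (dir in c(1, -1)) {
      j <- i
      while (j < n && dir * (sbp[j + 1] - sbp[j]) >= thr) j <- j + 1
      len <- j - i + 1
      if (len >= min_len) {
        if (i == 1 || !(dir * (sbp[i] - sbp[i - 1]) >= thr))
          found[[length(found) + 1L]] <- c(i, j, dir)
      }
    }
  }
  found
}
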