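test_that("signal-MAP correlation honors sign and matches the covariance
           oracle", {
  t <- seq(-60, 180, by = 0.04)
  map <- 90 - 20 * exp(-(t - 10)^2 / 40)
  df <- tibble::tibble(rep = 1L, t = t, signal = map, map = map)
  expect_equal(signal_map_correlation(df, onset = 0), 1)
  df$signal <- -map
  expect_equal(signal_map_correlation(df, onset = 0), -1)
  # random pairs vs direct covariance formula, after repeat averaging
  set.seed(5)
  for (i in 1:10) {
    d2 <- dplyr::bind_rows(lapply(1:3, function(r)
      tibble::tibble(rep = r, t = t, signal = rnorm(length(t)),
                     map = rnorm(length(t)))))
    r_mod <- signal_map_correlation(d2, onset = 0)
    avg <- stats::aggregate(cbind(signal, map) ~ t, d2, mean)
    avg <- avg[avg$t > 0 & avg$t <= 30, ]
    num <- mean(avg$signal * avg$map) - mean(avg$signal) * mean(avg$map)
    den <- sqrt((mean(avg$signal^2) - mean(avg$signal)^2) *
                  (mean(avg$map^2) - mean(avg$map)^2))
    expect_equal(r_mod, num / den, tolerance = 1e-12)
  }
  df0 <- tibble::tibble(rep = 1L, t = t, signal = 1, map = map)
  expect_error(signal_map_correlation(df0, onset = 0), "degenerate")
})

test_that("drop measurement is baseline mean minus post-onset minimum", {
  t <- seq(-60, 60, by = 0.04)
  expect_equal(compute_drop(t, rep(7, length(t)), 0)$drop, 0)
  x <- ifelse(t > 0, 130 - 20 * exp(-(t - 12)^2 / 20), 130)
  d <- compute_drop(t, x, 0)
  expect_equal(d$baseline_value, 130)
  expect_equal(d$nadir_value, 110, tolerance = 1e-6)
  expect_equal(d$drop, 20, tolerance = 1e-6)
  expect_equal(d$nadir_time, 12, tolerance = 0.05)
  expect_error(compute_drop(t[t > -10], x[t > -10], 0, baseline_s = 60),
               "cover")
})

test_that("BRS and CAR are ratios of drops, undefined below the
           denominator floor", {
  expect_equal(brs_drop(200, 20), 10)
  expect_equal(car_drop(8, 20), 0.4)
  expect_true(is.na(brs_drop(200, 0.5)))
  expect_true(is.na(car_drop(8, -3)))
  # negative numerator (signal rose) is retained with its sign
  expect_equal(brs_drop(-50, 20), -2.5)
})

test_that("5-SD leave-one-out outlier rule flags gross outliers only", {
  v <- c(10, 10.5, 9.8, 60)
  got <- discard_outlier_estimates(v)
  # direct leave-one-out arithmetic oracle
  oracle <- vapply(seq_along(v), function(i) {
    others <- v[-i]
    abs(v[i] - mean(others)) > 5 * sd(others)
  }, TRUE)
  expect_equal(got, oracle)
  expect_equal(got, c(FALSE, FALSE, FALSE, TRUE))
  expect_false(any(discard_outlier_estimates(rep(3.2, 5))))
  expect_false(any(discard_outlier_estimates(c(1, 100))))
  # sanity: on Gaussian cohorts the rule rarely removes anything
  set.seed(8)
  removed <- vapply(1:200, function(i)
    sum(discard_outlier_estimates(rnorm(16, 8, 2))), 0)
  expect_lt(mean(removed) / 16, 0.2)
})

test_that("cohort summary gives median and interpolated quartiles", {
  df <- tibble::tibble(g = "a", v = c(1, 2, 3, 4, 5))
  s <- cohort_summary(df, v, g)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  one <- cohort_summary(tibble::tibble(v = 7), v)
  expect_equal(one$median, 7)
  expect_equal(one$q1, 7)
  # sort-based linear-interpolation quantile oracle on random draws
  set.seed(3)
  x <- rnorm(37)
  s2 <- cohort_summary(tibble::tibble(v = x), v)
  xs <- sort(x)
  interp_q <- function(p) {
    h <- 1 + p * (length(xs) - 1)
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  expect_equal(s2$q1, interp_q(0.25), tolerance = 1e-12)
  expect_equal(s2$q3, interp_q(0.75), tolerance = 1e-12)
  expect_equal(s2$median, interp_q(0.5), tolerance = 1e-12)
})
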