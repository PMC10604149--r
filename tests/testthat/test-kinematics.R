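test_that("dual_trace validates its contract", {
  t <- seq(0, 0.7, by = 0.1)
  s <- seq(0, 0.007, length.out = 8)
  expect_s3_class(dual_trace(t, s, s), "dual_trace")
  expect_error(dual_trace(t[1:5], s[1:5], s[1:5]), class = "cuttleflow_invalid_input")
  expect_error(dual_trace(rev(t), s, s), class = "cuttleflow_invalid_input")
  expect_error(dual_trace(c(0, 0.1, 0.2, 0.31, 0.4, 0.5, 0.6, 0.7), s, s),
               class = "cuttleflow_invalid_input")
  expect_error(dual_trace(t, -s, s), class = "cuttleflow_invalid_input")
  expect_error(dual_trace(t, rev(s), s), class = "cuttleflow_invalid_input")
})

test_that("separation is |s1 - s2|, symmetric, and floor-masked", {
  t <- seq(0, 0.7, by = 0.1)
  s <- seq(0, 7e-3, length.out = 8)
  same <- dual_trace(t, s, s)
  ser <- separation(same, floor = 1e-5)
  expect_equal(ser$separation, rep(0, 8))
  expect_identical(n_valid(ser), 0L)
  expect_true(all(is.na(ser$log_separation)))

  tr <- dual_trace(t, s + 2e-3, s)
  sw <- dual_trace(t, s, s + 2e-3)
  expect_equal(separation(tr, 1e-5)$separation, separation(sw, 1e-5)$separation)

  lam0 <- 0.8
  ex <- make_exponential_trace(lam0, D0 = 1e-4, n = 50, dt = 0.05)
  ser <- separation(ex, floor = 1e-5)
  expect_identical(n_valid(ser), 50L)
  slopes <- diff(ser$log_separation) / diff(ser$times)
  expect_equal(slopes, rep(lam0, 49), tolerance = 1e-9)
})

test_that("local_log_slope recovers exact exponents for every admissible window", {
  for (lam0 in c(0.01, 0.1, 1)) {
    ex <- make_exponential_trace(lam0, n = 80, dt = 0.05)
    ser <- separation(ex, floor = 1e-5)
    for (w in c(5L, 7L, 9L)) {
      lam <- local_log_slope(ser, window = w, degree = 4L)
      expect_equal(nrow(lam), 80 - w + 1)
      expect_equal(lam$lambda_local, rep(lam0, 80 - w + 1), tolerance = 1e-9)
    }
  }
})

test_that("degree-4 window differentiates a quartic log-separation exactly", {
  n <- 60; dt <- 0.02
  t <- (seq_len(n) - 1) * dt
  # log D = p(t), a quartic; derivative known analytically
  p <- function(t) -8 + 0.5 * t + 2 * t^2 - 1.2 * t^3 + 0.3 * t^4
  dp <- function(t) 0.5 + 4 * t - 3.6 * t^2 + 1.2 * t^3
  d <- exp(p(t))
  base <- 0.001 + 0.01 * t
  tr <- dual_trace(t, base + d, base)
  ser <- separation(tr, floor = 1e-9)
  lam <- local_log_slope(ser, window = 7L, degree = 4L)
  expect_equal(lam$lambda_local, dp(lam$times), tolerance = 1e-6)
})

test_that("window weights agree with the signal package Savitzky-Golay filter", {
  ours <- cuttleflow:::sg_derivative_weights(7L, 4L)
  sg <- signal::sgolay(p = 4, n = 7, m = 1)
  expect_equal(ours, as.numeric(sg[4, ]), tolerance = 1e-10)
})

test_that("windows touching masked samples are skipped", {
  lam0 <- 0.5
  ex <- make_exponential_trace(lam0, D0 = 1e-4, n = 40, dt = 0.05)
  # poke a hole: force one mid-sample below the floor
  ex$s1[20] <- ex$s2[20]
  ser <- separation(ex, floor = 1e-5)
  expect_identical(n_valid(ser), 39L)
  lam <- local_log_slope(ser, window = 7L, degree = 4L)
  # two maximal valid runs of lengths 19 and 20 -> (19-6) + (20-6) windows
  expect_equal(nrow(lam), 13 + 14)
  expect_equal(lam$lambda_local, rep(lam0, 27), tolerance = 1e-9)
})

test_that("local_log_slope rejects bad windows and empty series", {
  ex <- make_exponential_trace(0.3, n = 20)
  ser <- separation(ex, floor = 1e-5)
  expect_error(local_log_slope(ser, window = 6L), class = "cuttleflow_invalid_parameter")
  expect_error(local_log_slope(ser, window = 3L, degree = 4L),
               class = "cuttleflow_invalid_parameter")
  t <- seq(0, 0.7, by = 0.1)
  s <- seq(0, 7e-3, length.out = 8)
  empty <- separation(dual_trace(t, s, s), floor = 1e-5)
  lam <- local_log_slope(empty)
  expect_identical(nrow(lam), 0L)
  expect_error(percentile_summary(lam), class = "cuttleflow_empty_input")
})

test_that("time-shift invariance and scale equivariance of the exponent chain", {
  lam0 <- 0.7
  ex <- make_exponential_trace(lam0, n = 60, dt = 0.05)
  shifted <- dual_trace(ex$times + 123.4, ex$s1, ex$s2)
  a <- local_log_slope(separation(ex, 1e-5))
  b <- local_log_slope(separation(shifted, 1e-5))
  expect_equal(a$lambda_local, b$lambda_local, tolerance = 1e-12)

  scaled <- dual_trace(ex$times, 3 * ex$s1, 3 * ex$s2)
  ser <- separation(ex, 1e-5)
  ser3 <- separation(scaled, 3e-5)
  expect_equal(ser3$separation, 3 * ser$separation)
  expect_equal(ser3$log_separation, ser$log_separation + log(3))
  expect_equal(local_log_slope(ser3)$lambda_local,
               local_log_slope(ser)$lambda_local, tolerance = 1e-9)
})

test_that("percentile_summary uses interpolated order statistics", {
  mk <- function(v) {
    structure(data.frame(times = seq_along(v), lambda_local = v),
              dt = 1, window = 7L, degree = 4L,
              class = c("lyapunov_series", "data.frame"))
  }
  expect_equal(percentile_summary(mk(c(1, 2, 3, 4)), 0.75)$lambda_q, 3.25)
  expect_equal(percentile_summary(mk(rep(2.5, 10)), 0.33)$lambda_q, 2.5)
  s <- mk(c(-1, 0.5, 2, 7, 3, -2, 4))
  expect_gte(percentile_summary(s, 0.75)$lambda_q,
             percentile_summary(s, 0.5)$lambda_q)
  pos <- percentile_summary(s, 0.75, positive_only = TRUE)
  expect_identical(pos$n_exponents, 5L)
  expect_error(percentile_summary(mk(numeric(0))), class = "cuttleflow_empty_input")
})

test_that("lambda_trend fits the condition slope and ignores ordering", {
  cond <- c(0.0057, 0.0114, 0.0133)
  lam <- 10 + 2000 * cond
  # exact-line fixture: summary.lm warns about the perfect fit, by design
  fit <- suppressWarnings(lambda_trend(cond, lam))
  expect_equal(fit$slope, 2000, tolerance = 1e-9)
  expect_equal(fit$std_error, 0, tolerance = 1e-6)
  perm <- c(3, 1, 2)
  expect_equal(suppressWarnings(lambda_trend(cond[perm], lam[perm]))$slope,
               fit$slope)
  expect_error(lambda_trend(c(1, 1, 1), c(1, 2, 3)), class = "cuttleflow_invalid_input")
})

test_that("crossing_count counts sign changes of the front difference", {
  t <- seq(0, 2, length.out = 41)
  base <- 0.001 + 0.01 * t
  offset <- dual_trace(t, base + 5e-4, base)
  expect_identical(crossing_count(offset), 0L)
  # oscillating difference with 4 zero crossings, riding on a steep ramp
  diffr <- 5e-4 * sin(2 * pi * t)  # crosses zero at t = 0.5, 1.0, 1.5, 2.0-
  tr <- dual_trace(t, base + pmax(diffr, 0) + 1e-5, base + pmax(-diffr, 0) + 2e-5,
                   monotone_tol = 1e-3)
  expect_identical(crossing_count(tr), 4L)
  # monotone separation: no crossings
  mono <- make_exponential_trace(0.5, n = 40)
  expect_identical(crossing_count(mono), 0L)
})
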