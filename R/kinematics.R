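#' Paired front-displacement trace
#'
#' Displacements S1(t), S2(t) of the two air-water fronts of a dual-channel
#' experiment on a uniform time grid, with the experiment's operating
#' condition (hydrostatic head and wall amplitude) carried as metadata.
#'
#' @param times Time grid, s; uniform spacing (relative deviation <= 1e-9),
#'   at least 8 samples.
#' @param s1,s2 Front displacements, m; non-negative and non-decreasing to
#'   within `monotone_tol`.
#' @param head Hydrostatic head ΔH of the run, m (metadata; may be `NA`).
#' @param amplitude Wall-corrugation amplitude A, m (metadata; may be `NA`).
#' @param label Free-text run label.
#' @param monotone_tol Permitted per-step decrease of a front, m
#'   (measurement noise allowance).
#' @return A `dual_trace` data frame (columns `times`, `s1`, `s2`) with
#'   attributes `dt`, `head`, `amplitude`, `label`.
#' @export
dual_trace <- function(times, s1, s2, head = NA_real_, amplitude = NA_real_,
                       label = "", monotone_tol = 1e-9) {
  n <- length(times)
  if (n < 8L || length(s1) != n || length(s2) != n) {
    abort_invalid_input("`times`, `s1`, `s2` must share length >= 8")
  }
  if (any(!is.finite(times)) || any(!is.finite(s1)) || any(!is.finite(s2))) {
    abort_invalid_input("trace arrays must be finite")
  }
  dt <- diff(times)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9 * abs(dt[1])) {
    abort_invalid_input("`times` must be a uniform, strictly increasing grid")
  }
  if (any(s1 < 0) || any(s2 < 0)) {
    abort_invalid_input("front displacements must be non-negative")
  }
  if (any(diff(s1) < -monotone_tol) || any(diff(s2) < -monotone_tol)) {
    abort_invalid_input("front displacements must be non-decreasing (within `monotone_tol`)")
  }
  structure(
    data.frame(times = times, s1 = s1, s2 = s2),
    dt = dt[1], head = head, amplitude = amplitude, label = label,
    class = c("dual_trace", "data.frame"))
}

assert_dual_trace <- function(trace) {
  if (!inherits(trace, "dual_trace")) {
    abort_invalid_input("expected a `dual_trace` object")
  }
  invisible(trace)
}

#' Front separation series D(t)
#'
#' The separation between the two front ends, D(t) = |S1(t) - S2(t)|; the
#' absolute value removes any bias toward a specific channel. Samples with
#' D below `floor` (crossings and sub-resolution separations, where log D
#' is meaningless) are masked out: `log_separation` is `NA` there and
#' `valid` is `FALSE`. A series with no valid sample is returned as an
#' empty-but-well-formed object, distinguishable via [n_valid()].
#'
#' @param trace A [dual_trace()].
#' @param floor Smallest resolvable separation, m; defaults to one pixel of
#'   the default synthetic rendering (25 um).
#' @return A `separation_series` data frame with columns `times`,
#'   `separation`, `log_separation`, `valid`; attributes `dt` and `floor`.
#' @export
separation <- function(trace, floor = 2.5e-5) {
  assert_dual_trace(trace)
  check_scalar(floor, "floor", lower = 0, strict_lower = TRUE)
  d <- abs(trace$s1 - trace$s2)
  valid <- d >= floor
  logd <- rep(NA_real_, length(d))
  logd[valid] <- log(d[valid])
  structure(
    data.frame(times = trace$times, separation = d,
               log_separation = logd, valid = valid),
    dt = attr(trace, "dt"), floor = floor,
    head = attr(trace, "head"), amplitude = attr(trace, "amplitude"),
    class = c("separation_series", "data.frame"))
}

#' Number of valid (unmasked) samples of a separation series
#' @param series A `separation_series`.
#' @return Integer count.
#' @export
n_valid <- function(series) {
  if (!inherits(series, "separation_series")) {
    abort_invalid_input("expected a `separation_series`")
  }
  sum(series$valid)
}

# First-derivative weights of a centred Savitzky-Golay filter: least-squares
# fit of a degree-`degree` polynomial over `window` points, derivative
# evaluated at the centre. Row 2 of the pseudoinverse of the Vandermonde
# matrix in the centred coordinate.
sg_derivative_weights <- function(window, degree) {
  k <- (window - 1L) %/% 2L
  x <- seq.int(-k, k)
  X <- outer(x, 0:degree, `^`)
  solve(crossprod(X), t(X))[2L, ]
}

#' Local slope of log D(t): the local Lyapunov exponent
#'
#' The exponent of separation lambda in D(t) = exp(lambda t) is estimated
#' locally, since any single choice of t in log(D)/t is arbitrary: over
#' every fully valid centred window of `window` samples, a polynomial of
#' order `degree` is least-squares fitted to log D (a Savitzky-Golay
#' sliding-window differentiator) and its first derivative at the window
#' centre, divided by the sample spacing, is the local exponent in 1/s.
#' Windows containing any masked sample are skipped, so exponents exist
#' only at full-window centres: a fully valid series of length N yields
#' exactly N - window + 1 exponents.
#'
#' @param series A [separation()] series.
#' @param window Odd window length, >= degree + 1 (default 7).
#' @param degree Polynomial order of the fit (default 4).
#' @return A `lyapunov_series` data frame with columns `times` (window
#'   centres, s) and `lambda_local` (1/s). Zero rows if no fully valid
#'   window exists.
#' @export
local_log_slope <- function(series, window = 7L, degree = 4L) {
  if (!inherits(series, "separation_series")) {
    abort_invalid_input("expected a `separation_series`")
  }
  window <- as.integer(window)
  degree <- as.integer(degree)
  if (is.na(window) || window %% 2L == 0L || window < degree + 1L) {
    abort_invalid_parameter("`window` must be odd and >= degree + 1")
  }
  if (degree < 1L) abort_invalid_parameter("`degree` must be >= 1")
  dt <- attr(series, "dt")
  w1 <- sg_derivative_weights(window, degree)
  k <- (window - 1L) %/% 2L
  n <- nrow(series)
  centres <- integer(0)
  if (n >= window) {
    cand <- (k + 1L):(n - k)
    # a centre is usable iff all `window` samples around it are valid
    full <- vapply(cand, function(i) all(series$valid[(i - k):(i + k)]), logical(1))
    centres <- cand[full]
  }
  lam <- vapply(centres, function(i) {
    sum(w1 * series$log_separation[(i - k):(i + k)]) / dt
  }, numeric(1))
  structure(
    data.frame(times = series$times[centres], lambda_local = lam),
    dt = dt, window = window, degree = degree,
    head = attr(series, "head"), amplitude = attr(series, "amplitude"),
    class = c("lyapunov_series", "data.frame"))
}

#' Upper-quantile summary of local Lyapunov exponents
#'
#' A single experiment yields of order 150-300 local exponents; the run is
#' summarized by an upper quantile (default the 75th percentile), which
#' captures the fastest separation phases. Positive values indicate
#' episodes where the two fronts separate exponentially.
#'
#' @param series A [local_log_slope()] result.
#' @param quantile Quantile level in (0, 1), default 0.75. Linear
#'   interpolation between closest order statistics
#'   (`stats::quantile(type = 7)`).
#' @param positive_only If `TRUE`, restrict to positive exponents before
#'   taking the quantile.
#' @return A `lyapunov_summary` list: `lambda_q` (1/s), `n_exponents`,
#'   `quantile`.
#' @export
percentile_summary <- function(series, quantile = 0.75, positive_only = FALSE) {
  if (!inherits(series, "lyapunov_series")) {
    abort_invalid_input("expected a `lyapunov_series`")
  }
  check_scalar(quantile, "quantile", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  lam <- series$lambda_local
  if (positive_only) lam <- lam[lam > 0]
  if (length(lam) == 0L) {
    abort_empty_input("no Lyapunov exponents to summarize")
  }
  structure(
    list(lambda_q = unname(stats::quantile(lam, quantile, type = 7)),
         n_exponents = length(lam), quantile = quantile),
    class = "lyapunov_summary")
}

#' @export
print.lyapunov_summary <- function(x, ...) {
  cat(sprintf("lambda (q = %.2f): %.4g 1/s over %d local exponents\n",
              x$quantile, x$lambda_q, x$n_exponents))
  invisible(x)
}

#' Trend of summary exponents across an experimental condition
#'
#' Ordinary least-squares slope of the per-run summary exponent against a
#' condition value (hydrostatic head or wall amplitude), with its standard
#' error. A positive slope reproduces the qualitative finding that larger
#' pressure drops, and wavier walls, separate the fronts faster.
#'
#' @param conditions Numeric condition values (m), one per run; at least
#'   two distinct values.
#' @param summaries A list of `lyapunov_summary` objects, or a numeric
#'   vector of summary exponents, aligned with `conditions`.
#' @return A `trend_fit` list: `slope` (1/s per condition unit),
#'   `std_error`, `intercept`, `n`.
#' @export
lambda_trend <- function(conditions, summaries) {
  if (is.list(summaries)) {
    ok <- vapply(summaries, inherits, logical(1), "lyapunov_summary")
    if (!all(ok)) abort_invalid_input("`summaries` must be lyapunov_summary objects")
    lam <- vapply(summaries, function(s) s$lambda_q, numeric(1))
  } else {
    lam <- as.numeric(summaries)
  }
  if (!is.numeric(conditions) || length(conditions) != length(lam)) {
    abort_invalid_input("`conditions` must be numeric and aligned with `summaries`")
  }
  if (length(unique(conditions)) < 2L) {
    abort_invalid_input("need at least 2 distinct condition values")
  }
  fit <- stats::lm(lam ~ conditions)
  cf <- stats::coef(summary(fit))
  structure(
    list(slope = cf["conditions", "Estimate"],
         std_error = cf["conditions", "Std. Error"],
         intercept = cf["(Intercept)", "Estimate"],
         n = length(lam)),
    class = "trend_fit")
}

#' Count front crossings
#'
#' Number of sign changes of S1 - S2, i.e. events where the lagging front
#' overtakes the leading one. Samples with |S1 - S2| below `floor` are
#' ignored so that dwelling near zero is not counted as chatter.
#'
#' @param trace A [dual_trace()].
#' @param floor Separation below which samples are ignored, m (default 0:
#'   only exact ties are dropped).
#' @return Integer crossing count.
#' @export
crossing_count <- function(trace, floor = 0) {
  assert_dual_trace(trace)
  check_scalar(floor, "floor", lower = 0)
  d <- trace$s1 - trace$s2
  d <- d[abs(d) > floor]
  if (length(d) < 2L) return(0L)
  sum(diff(sign(d)) != 0)
}
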