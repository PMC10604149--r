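#' Capillary-rise model for a single gap
#'
#' Parameters of the momentum balance for liquid rising in a narrow gap of
#' width w:
#'
#'   rho * d(z * dz/dt)/dt = 2 sigma cos(theta) / w - mu * z * (dz/dt) / w^2
#'
#' Inertia balances surface tension at early times (linear growth
#' z = U0 t with U0 = sqrt(2 sigma cos(theta) / (rho w))); viscous drag
#' takes over past the crossover time t_c = rho w^2 / mu, after which
#' z = sqrt(4 sigma cos(theta) w t / mu), the Washburn square-root law.
#'
#' @param fluid A [fluid_properties()] object.
#' @param gap_width Characteristic gap width w, m (> 0).
#' @param initial_height z at t = 0, m (>= 0).
#' @param initial_speed dz/dt at t = 0, m/s.
#' @param poiseuille_factor Multiplier on the viscous term; 1 integrates
#'   the balance exactly as written above, 12 gives the parallel-plate
#'   Poiseuille convention.
#' @return An object of class `washburn_model`.
#' @export
washburn_model <- function(fluid, gap_width, initial_height = 0,
                           initial_speed = 0, poiseuille_factor = 1) {
  assert_fluid(fluid)
  check_scalar(gap_width, "gap_width", lower = 0, strict_lower = TRUE)
  check_scalar(initial_height, "initial_height", lower = 0)
  check_scalar(initial_speed, "initial_speed")
  check_scalar(poiseuille_factor, "poiseuille_factor", lower = 0,
               strict_lower = TRUE)
  structure(
    list(fluid = fluid, gap_width = gap_width,
         initial_height = initial_height, initial_speed = initial_speed,
         poiseuille_factor = poiseuille_factor),
    class = "washburn_model")
}

# forcing (2 sigma cos theta / w), damping coefficient (pf mu / w^2) and
# the inertial-viscous crossover time of a model
washburn_coefficients <- function(model) {
  f <- model$fluid
  forcing <- 2 * f$surface_tension * cos(f$contact_angle) / model$gap_width
  damping <- model$poiseuille_factor * f$viscosity / model$gap_width^2
  list(forcing = forcing, damping = damping,
       crossover_time = f$density / damping,
       initial_speed_limit = sqrt(max(forcing, 0) / f$density))
}

#' Crossover time between the linear and Washburn regimes
#'
#' `t_c = rho w^2 / (poiseuille_factor * mu)`, the only timescale shared by
#' the inertia-surface-tension and viscous-surface-tension balances.
#'
#' @param model A [washburn_model()].
#' @return Time, s.
#' @export
washburn_crossover_time <- function(model) {
  if (!inherits(model, "washburn_model")) {
    abort_invalid_parameter("`model` must be a `washburn_model`")
  }
  washburn_coefficients(model)$crossover_time
}

new_rise_trace <- function(times, heights, speeds) {
  structure(
    data.frame(times = times, heights = heights, speeds = speeds),
    class = c("rise_trace", "data.frame"))
}

assert_rise_trace <- function(trace) {
  if (!inherits(trace, "rise_trace")) {
    abort_invalid_input("expected a `rise_trace` object")
  }
  if (any(!is.finite(trace$times)) || is.unsorted(trace$times, strictly = TRUE)) {
    abort_invalid_input("`times` must be a finite, strictly increasing grid")
  }
  if (any(trace$heights < 0)) {
    abort_invalid_input("`heights` must be non-negative")
  }
  invisible(trace)
}

#' Integrate the capillary-rise momentum equation
#'
#' Integrates the momentum variable y = z * dz/dt, in which the balance is
#' regular at z = 0 (the equation as written divides by nothing):
#' rho dy/dt = 2 sigma cos(theta)/w - pf * mu * y / w^2, with
#' y(0) = z(0) * zdot(0). The height is recovered from
#' z(t)^2 = z(0)^2 + 2 * integral of y, integrated alongside y. Adaptive
#' lsoda stepping with absolute tolerance 1e-12 on y.
#'
#' @param model A [washburn_model()].
#' @param times Output time grid, s; must start at 0 and be strictly
#'   increasing.
#' @return A `rise_trace` data frame with columns `times`, `heights` (z, m)
#'   and `speeds` (dz/dt, m/s).
#' @examples
#' w <- washburn_model(fluid_properties(), gap_width = 1e-4)
#' tr <- integrate_washburn(w, seq(0, 1, by = 1e-3))
#' @export
integrate_washburn <- function(model, times) {
  if (!inherits(model, "washburn_model")) {
    abort_invalid_parameter("`model` must be a `washburn_model`")
  }
  if (!is.numeric(times) || length(times) < 2L || times[1] != 0 ||
      is.unsorted(times, strictly = TRUE)) {
    abort_invalid_parameter("`times` must start at 0 and be strictly increasing")
  }
  co <- washburn_coefficients(model)
  rho <- model$fluid$density
  y0 <- model$initial_height * model$initial_speed
  state <- c(y = y0, m = 0)
  deriv <- function(t, state, parms) {
    list(c(y = (co$forcing - co$damping * state[["y"]]) / rho,
           m = state[["y"]]))
  }
  sol <- tryCatch(
    deSolve::ode(y = state, times = times, func = deriv, parms = NULL,
                 method = "lsoda", atol = 1e-12, rtol = 1e-10),
    warning = function(w) {
      abort_numerical_failure(paste("capillary-rise integration failed:",
                                    conditionMessage(w)))
    })
  if (nrow(sol) < length(times)) {
    abort_numerical_failure(
      sprintf("integration stopped at t = %g s (of %g s requested)",
              sol[nrow(sol), "time"], times[length(times)]),
      last_state = sol[nrow(sol), ])
  }
  z <- sqrt(pmax(model$initial_height^2 + 2 * sol[, "m"], 0))
  # dz/dt = y / z; at z = 0 the limit is the inertial speed U0
  speeds <- ifelse(z > 0, sol[, "y"] / z, co$initial_speed_limit)
  new_rise_trace(times, z, speeds)
}

#' Residual of the momentum balance along a trace
#'
#' Evaluates rho * d(z zdot)/dt - [2 sigma cos(theta)/w - pf mu z zdot/w^2]
#' by fourth-order central finite differences of y = z * zdot on the trace
#' grid, and returns it relative to the forcing term. A correctly
#' integrated trace on a reasonably fine grid has a relative residual many
#' orders of magnitude below 1.
#'
#' @param trace A `rise_trace` from [integrate_washburn()] (uniform grid).
#' @param model The `washburn_model` it came from.
#' @return Numeric vector of relative residuals at interior grid points.
#' @export
washburn_residual <- function(trace, model) {
  assert_rise_trace(trace)
  co <- washburn_coefficients(model)
  t <- trace$times
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
    abort_invalid_input("residual evaluation requires a uniform time grid")
  }
  y <- trace$heights * trace$speeds
  n <- length(y)
  if (n < 5L) abort_invalid_input("need at least 5 samples")
  i <- 3:(n - 2)
  dydt <- (-y[i + 2] + 8 * y[i + 1] - 8 * y[i - 1] + y[i - 2]) / (12 * dt[1])
  res <- model$fluid$density * dydt - (co$forcing - co$damping * y[i])
  res / co$forcing
}

#' Normalize a rise trace by its final time and displacement
#'
#' Rescales so the last sample is exactly (1, 1), the presentation used to
#' collapse penetration curves from different samples onto a common axis.
#' Idempotent.
#'
#' @param trace A `rise_trace`.
#' @return A dimensionless `rise_trace`.
#' @export
normalize_trace <- function(trace) {
  assert_rise_trace(trace)
  tf <- trace$times[nrow(trace)]
  zf <- trace$heights[nrow(trace)]
  if (tf <= 0) abort_invalid_input("final time must be positive")
  if (zf <= 0) abort_invalid_input("final displacement must be positive")
  new_rise_trace(trace$times / tf, trace$heights / zf,
                 trace$speeds * tf / zf)
}

#' Fit the power-law exponent of a rise trace
#'
#' Least-squares slope of log z versus log t over a fractional window of
#' the time span. Pure inertial growth gives 1, the Washburn regime gives
#' 1/2; a window straddling the crossover gives a value strictly between.
#'
#' @param trace A `rise_trace`.
#' @param fit_range Length-2 fractions of the time span, e.g. `c(0.5, 1)`
#'   for the second half.
#' @return Exponent (dimensionless scalar).
#' @export
fit_rise_exponent <- function(trace, fit_range = c(0, 1)) {
  assert_rise_trace(trace)
  if (!is.numeric(fit_range) || length(fit_range) != 2L ||
      fit_range[1] < 0 || fit_range[2] > 1 || fit_range[1] >= fit_range[2]) {
    abort_invalid_parameter("`fit_range` must be fractions with 0 <= lo < hi <= 1")
  }
  t0 <- trace$times[1]
  span <- trace$times[nrow(trace)] - t0
  lo <- t0 + fit_range[1] * span
  hi <- t0 + fit_range[2] * span
  sel <- trace$times >= lo & trace$times <= hi &
    trace$times > 0 & trace$heights > 0
  if (sum(sel) < 5L) {
    abort_invalid_input("need at least 5 samples with t > 0 and z > 0 in the fit range")
  }
  unname(stats::coef(stats::lm(log(trace$heights[sel]) ~ log(trace$times[sel])))[2])
}
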