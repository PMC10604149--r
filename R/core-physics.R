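#' Fluid properties
#'
#' Bundles the physical properties of the working fluid. Defaults describe
#' water on a wetting (glass/PDMS) surface: density 997 kg/m^3, dynamic
#' viscosity 1e-3 Pa s, surface tension 0.072 N/m, contact angle 0
#' (complete wetting), g = 9.81 m/s^2. All values SI.
#'
#' @param density Mass density, kg/m^3. Must be > 0.
#' @param viscosity Dynamic viscosity, Pa s. Must be > 0.
#' @param surface_tension Surface tension, N/m. Must be >= 0.
#' @param contact_angle Equilibrium contact angle, radians, in `[0, pi/2)`.
#' @param gravity Gravitational acceleration, m/s^2. Must be > 0.
#' @return An object of class `fluid_properties`.
#' @examples
#' water <- fluid_properties()
#' reynolds_number(water, speed = 300e-6, length_scale = 100e-6)
#' @export
fluid_properties <- function(density = 997, viscosity = 1e-3,
                             surface_tension = 0.072, contact_angle = 0,
                             gravity = 9.81) {
  check_scalar(density, "density", lower = 0, strict_lower = TRUE)
  check_scalar(viscosity, "viscosity", lower = 0, strict_lower = TRUE)
  check_scalar(surface_tension, "surface_tension", lower = 0)
  check_scalar(contact_angle, "contact_angle", lower = 0, upper = pi / 2,
               strict_upper = TRUE)
  check_scalar(gravity, "gravity", lower = 0, strict_lower = TRUE)
  structure(
    list(density = density, viscosity = viscosity,
         surface_tension = surface_tension, contact_angle = contact_angle,
         gravity = gravity),
    class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("Fluid properties (SI):\n")
  cat(sprintf("  density         %g kg/m^3\n", x$density))
  cat(sprintf("  viscosity       %g Pa s\n", x$viscosity))
  cat(sprintf("  surface tension %g N/m\n", x$surface_tension))
  cat(sprintf("  contact angle   %g rad\n", x$contact_angle))
  cat(sprintf("  gravity         %g m/s^2\n", x$gravity))
  invisible(x)
}

assert_fluid <- function(fluid) {
  if (!inherits(fluid, "fluid_properties")) {
    abort_invalid_parameter("`fluid` must be a `fluid_properties` object")
  }
  invisible(fluid)
}

#' Reynolds number
#'
#' Ratio of fluid inertia to viscous force, rho * U * L / mu. For water
#' moving at hundreds of micrometres per second through channels of
#' 0.1-0.75 mm this is well below 1, so the interface motion is viscosity
#' dominated.
#'
#' @param fluid A [fluid_properties()] object.
#' @param speed Interface speed U, m/s (>= 0).
#' @param length_scale Characteristic length L, m (> 0).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(fluid, speed, length_scale) {
  assert_fluid(fluid)
  check_scalar(speed, "speed", lower = 0)
  check_scalar(length_scale, "length_scale", lower = 0, strict_lower = TRUE)
  fluid$density * speed * length_scale / fluid$viscosity
}

#' Hydrostatic driving pressure
#'
#' The pressure drop imposed by lowering the fluid bath a height `ΔH`
#' below the channel: `ΔP = rho * g * ΔH`.
#'
#' @inheritParams reynolds_number
#' @param height_difference Bath lowering `ΔH`, m (>= 0 by the sign
#'   convention that the bath sits below the channel).
#' @return Pressure, Pa.
#' @export
hydrostatic_pressure <- function(fluid, height_difference) {
  assert_fluid(fluid)
  check_scalar(height_difference, "height_difference", lower = 0)
  fluid$density * fluid$gravity * height_difference
}

#' Capillary pressure across a curved interface
#'
#' `2 * gamma / R` for an interface of radius of curvature R. In a dual
#' channel of equal width the two menisci share the same R, so the
#' capillary pressure difference between the channels is exactly zero.
#'
#' @inheritParams reynolds_number
#' @param radius_of_curvature Meniscus radius of curvature R, m (> 0).
#' @return Pressure, Pa.
#' @export
capillary_pressure <- function(fluid, radius_of_curvature) {
  assert_fluid(fluid)
  check_scalar(radius_of_curvature, "radius_of_curvature", lower = 0,
               strict_lower = TRUE)
  2 * fluid$surface_tension / radius_of_curvature
}

#' Viscous (Poiseuille) pressure drop along the filled channel
#'
#' Scales as `mu * L * U / h^2` with the water-filled length L, interface
#' speed U and gap h. At the study's scales this is 1e-2 to 1e-1 Pa, two
#' to four orders below the hydrostatic driving pressure.
#'
#' @inheritParams reynolds_number
#' @param filled_length Water-filled channel length L, m (>= 0).
#' @param speed Interface speed U, m/s (>= 0).
#' @param gap Channel width/height h, m (> 0).
#' @return Pressure, Pa.
#' @export
viscous_pressure <- function(fluid, filled_length, speed, gap) {
  assert_fluid(fluid)
  check_scalar(filled_length, "filled_length", lower = 0)
  check_scalar(speed, "speed", lower = 0)
  check_scalar(gap, "gap", lower = 0, strict_lower = TRUE)
  fluid$viscosity * filled_length * speed / gap^2
}

#' Contact-line pressure drop
#'
#' Dissipation from shearing the fluid wedge between wall and meniscus,
#' proportional to `mu * U / h`. The proportionality constant is not fixed
#' by the scaling argument; it defaults to 1 and can be overridden.
#'
#' @inheritParams viscous_pressure
#' @param coefficient Dimensionless prefactor, default 1.
#' @return Pressure, Pa.
#' @export
contact_line_pressure <- function(fluid, speed, gap, coefficient = 1) {
  assert_fluid(fluid)
  check_scalar(speed, "speed", lower = 0)
  check_scalar(gap, "gap", lower = 0, strict_lower = TRUE)
  check_scalar(coefficient, "coefficient", lower = 0)
  coefficient * fluid$viscosity * speed / gap
}

#' Gauge pressure at the channel head
#'
#' The liquid bath fixes the pressure at the head of the channels to
#' `P_atm - rho*g*ΔH - 2*gamma/R`; this function returns the gauge value
#' `-(rho*g*ΔH + 2*gamma/R)` (atmosphere = 0), which is what drives the
#' interface toward the head. It is always <= 0 for `ΔH >= 0`.
#'
#' @inheritParams hydrostatic_pressure
#' @param radius_of_curvature Meniscus radius of curvature, m (> 0); pass
#'   `Inf` for a flat interface.
#' @return Gauge pressure, Pa (non-positive).
#' @export
head_pressure <- function(fluid, height_difference, radius_of_curvature) {
  assert_fluid(fluid)
  check_scalar(height_difference, "height_difference", lower = 0)
  if (!(is.numeric(radius_of_curvature) && length(radius_of_curvature) == 1L &&
        !is.na(radius_of_curvature) && radius_of_curvature > 0)) {
    abort_invalid_parameter("`radius_of_curvature` must be a positive scalar (Inf allowed)")
  }
  cap <- if (is.finite(radius_of_curvature)) {
    capillary_pressure(fluid, radius_of_curvature)
  } else 0
  -(hydrostatic_pressure(fluid, height_difference) + cap)
}

#' Full pressure budget for a dual-channel experiment
#'
#' Assembles the hydrostatic driving pressure and the three interface
#' pressure components (capillary, viscous, contact line) for one operating
#' point, together with the diagnostic ratios viscous/hydrostatic and
#' contact-line/viscous. At the nominal operating conditions of the study
#' (U of order 1 mm/s, h = 0.75 mm, L <= 3.9 cm, heads of 0.57-1.33 cm)
#' the hierarchy hydrostatic >> viscous >> contact line holds, which is why
#' the two channels are driven essentially identically.
#'
#' @inheritParams viscous_pressure
#' @param height_difference Bath lowering, m.
#' @param radius_of_curvature Meniscus radius of curvature, m.
#' @param contact_line_coefficient Prefactor for the contact-line term.
#' @return A `pressure_budget` object (list with fields `hydrostatic`,
#'   `capillary`, `viscous`, `contact_line`, `head_pressure`, all Pa, and
#'   ratios `viscous_over_hydrostatic`, `contact_line_over_viscous`).
#' @examples
#' water <- fluid_properties()
#' pressure_budget(water, height_difference = 0.0133,
#'                 radius_of_curvature = 0.375e-3,
#'                 filled_length = 0.039, speed = 1e-3, gap = 0.75e-3)
#' @export
pressure_budget <- function(fluid, height_difference, radius_of_curvature,
                            filled_length, speed, gap,
                            contact_line_coefficient = 1) {
  hydro <- hydrostatic_pressure(fluid, height_difference)
  cap <- capillary_pressure(fluid, radius_of_curvature)
  visc <- viscous_pressure(fluid, filled_length, speed, gap)
  cl <- contact_line_pressure(fluid, speed, gap, contact_line_coefficient)
  budget <- list(
    hydrostatic = hydro,
    capillary = cap,
    viscous = visc,
    contact_line = cl,
    head_pressure = head_pressure(fluid, height_difference, radius_of_curvature),
    viscous_over_hydrostatic = if (hydro > 0) visc / hydro else NA_real_,
    contact_line_over_viscous = if (visc > 0) cl / visc else NA_real_)
  structure(budget, class = "pressure_budget")
}

#' @export
print.pressure_budget <- function(x, ...) {
  cat("Pressure budget (Pa):\n")
  cat(sprintf("  hydrostatic   %12.4g\n", x$hydrostatic))
  cat(sprintf("  capillary     %12.4g\n", x$capillary))
  cat(sprintf("  viscous       %12.4g\n", x$viscous))
  cat(sprintf("  contact line  %12.4g\n", x$contact_line))
  cat(sprintf("  head (gauge)  %12.4g\n", x$head_pressure))
  if (is.finite(x$viscous_over_hydrostatic %||% NA_real_)) {
    cat(sprintf("  viscous/hydrostatic  %.3g\n", x$viscous_over_hydrostatic))
  }
  if (is.finite(x$contact_line_over_viscous %||% NA_real_)) {
    cat(sprintf("  contact-line/viscous %.3g\n", x$contact_line_over_viscous))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
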