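# Shared fixtures and independent oracles.

test_fluid <- function(...) fluid_properties(...)

# Closed-form solution of the capillary-rise momentum balance. The balance
# is linear in the momentum variable y = z*zdot:
#   rho y' = F - c y,  F = 2 sigma cos(theta)/w,  c = pf*mu/w^2
# so y(t) = y_inf + (y0 - y_inf) exp(-t/tau), tau = rho/c, y_inf = F/c,
# and z(t)^2 = z0^2 + 2 * integral(y). Independent of the deSolve route.
washburn_closed_form <- function(model, times) {
  f <- model$fluid
  forcing <- 2 * f$surface_tension * cos(f$contact_angle) / model$gap_width
  damping <- model$poiseuille_factor * f$viscosity / model$gap_width^2
  tau <- f$density / damping
  y_inf <- forcing / damping
  y0 <- model$initial_height * model$initial_speed
  int_y <- y_inf * times + (y0 - y_inf) * tau * (1 - exp(-times / tau))
  sqrt(pmax(model$initial_height^2 + 2 * int_y, 0))
}

# Closed-form front position for a straight channel, no noise, no
# capillary term: (Ltot + Lref - S) dS/dt = k is separable, so
# (Ltot + Lref - S)^2 = (Ltot + Lref - S0)^2 - 2 k t.
darcy_closed_form <- function(times, geometry, fluid, head, l_ref, s0 = 0) {
  k <- geometry$nominal_width^2 / (12 * fluid$viscosity) *
    hydrostatic_pressure(fluid, head)
  a0 <- geometry$total_length + l_ref - s0
  s <- geometry$total_length + l_ref - sqrt(pmax(a0^2 - 2 * k * times, 0))
  pmin(s, geometry$total_length)
}

# Dual trace whose separation is exactly D0 * exp(lambda * t), riding on a
# common monotone ramp so both fronts are valid displacements.
make_exponential_trace <- function(lambda, D0 = 1e-4, n = 100, dt = 0.05,
                                   ramp = 1e-3) {
  t <- (seq_len(n) - 1) * dt
  base <- 0.001 + ramp * t
  dual_trace(times = t, s1 = base + D0 * exp(lambda * t), s2 = base)
}

default_sim_setup <- function(amplitude = 0.188e-3, head = 1.33e-2,
                              seed = 11L, ...) {
  list(fluid = fluid_properties(),
       geometry = channel_geometry(amplitude = amplitude),
       config = simulation_config(head_height = head, seed = seed, ...))
}
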