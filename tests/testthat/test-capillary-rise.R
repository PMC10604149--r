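water <- fluid_properties()

test_that("integrated trace matches the closed-form solution", {
  model <- washburn_model(water, gap_width = 1e-4)
  tau <- washburn_crossover_time(model)
  times <- seq(0, 50 * tau, length.out = 400)
  tr <- integrate_washburn(model, times)
  expect_s3_class(tr, "rise_trace")
  z_ref <- washburn_closed_form(model, times)
  expect_equal(tr$heights[-1], z_ref[-1], tolerance = 1e-7)
  # non-zero start and non-zero initial speed too
  m2 <- washburn_model(water, gap_width = 2e-4, initial_height = 1e-3,
                       initial_speed = 5e-3)
  t2 <- seq(0, 1, length.out = 200)
  expect_equal(integrate_washburn(m2, t2)$heights,
               washburn_closed_form(m2, t2), tolerance = 1e-7)
})

test_that("zero surface tension gives no rise", {
  dry <- fluid_properties(surface_tension = 0)
  model <- washburn_model(dry, gap_width = 1e-4, initial_height = 2e-3)
  tr <- integrate_washburn(model, seq(0, 1, length.out = 50))
  expect_equal(tr$heights, rep(2e-3, 50), tolerance = 1e-12)
})

test_that("early-time limit is linear growth at U0", {
  model <- washburn_model(water, gap_width = 1e-4)
  tau <- washburn_crossover_time(model)
  U0 <- sqrt(2 * water$surface_tension * cos(water$contact_angle) /
               (water$density * model$gap_width))
  times <- c(0, seq(tau / 1e4, tau / 20, length.out = 50))
  tr <- integrate_washburn(model, times)
  rel <- abs(tr$heights[-1] / (U0 * times[-1]) - 1)
  expect_lt(max(rel), 0.01)
})

test_that("late-time limit is the Washburn square-root law", {
  model <- washburn_model(water, gap_width = 1e-4)
  tau <- washburn_crossover_time(model)
  times <- seq(0, 500 * tau, length.out = 300)
  tr <- integrate_washburn(model, times)
  late <- times >= 100 * tau
  z_washburn <- sqrt(4 * water$surface_tension * cos(water$contact_angle) *
                       model$gap_width * times[late] / water$viscosity)
  rel <- abs(tr$heights[late] / z_washburn - 1)
  expect_lt(max(rel), 0.01)
})

test_that("finite-difference residual of the balance is tiny", {
  model <- washburn_model(water, gap_width = 1e-4)
  tau <- washburn_crossover_time(model)
  tr <- integrate_washburn(model, seq(0, 5 * tau, by = tau / 100))
  expect_lt(max(abs(washburn_residual(tr, model))), 1e-6)
})

test_that("solution is invariant under nondimensional rescaling", {
  # equal dimensionless group beta = mu / sqrt(2 rho sigma cos(theta) w)
  # implies identical z/w versus t/T curves, T = sqrt(rho w^3 / (2 sigma cos theta))
  m1 <- washburn_model(water, gap_width = 1e-4)
  f2 <- fluid_properties(viscosity = water$viscosity * 2)
  m2 <- washburn_model(f2, gap_width = 4e-4)
  tconst <- function(m) {
    sqrt(m$fluid$density * m$gap_width^3 /
           (2 * m$fluid$surface_tension * cos(m$fluid$contact_angle)))
  }
  tstar <- seq(0, 2000, length.out = 150)
  tr1 <- integrate_washburn(m1, tstar * tconst(m1))
  tr2 <- integrate_washburn(m2, tstar * tconst(m2))
  expect_equal(tr1$heights / m1$gap_width, tr2$heights / m2$gap_width,
               tolerance = 1e-6)
})

test_that("heights are monotone and speed eventually decreases", {
  model <- washburn_model(water, gap_width = 1e-4)
  tau <- washburn_crossover_time(model)
  tr <- integrate_washburn(model, seq(0, 100 * tau, length.out = 500))
  expect_true(all(diff(tr$heights) >= 0))
  late_speeds <- tr$speeds[tr$times > 10 * tau]
  expect_true(all(diff(late_speeds) < 0))
})

test_that("poiseuille_factor rescales the viscous term", {
  m12 <- washburn_model(water, gap_width = 1e-4, poiseuille_factor = 12)
  times <- seq(0, 1, length.out = 100)
  expect_equal(integrate_washburn(m12, times)$heights,
               washburn_closed_form(m12, times), tolerance = 1e-7)
  expect_equal(washburn_crossover_time(m12),
               washburn_crossover_time(washburn_model(water, 1e-4)) / 12)
})

test_that("normalize_trace lands on (1,1), is idempotent, preserves shape", {
  model <- washburn_model(water, gap_width = 1e-4)
  tr <- integrate_washburn(model, seq(0, 1, length.out = 100))
  nz <- normalize_trace(tr)
  expect_equal(nz$times[nrow(nz)], 1)
  expect_equal(nz$heights[nrow(nz)], 1)
  expect_equal(normalize_trace(nz), nz, tolerance = 1e-12, ignore_attr = TRUE)
  # a pure-Washburn trace normalizes onto sqrt(normalized time)
  t <- seq(0, 4, length.out = 64)
  pure <- structure(data.frame(times = t, heights = 3 * sqrt(t),
                               speeds = c(0, 1.5 / sqrt(t[-1]))),
                    class = c("rise_trace", "data.frame"))
  np <- normalize_trace(pure)
  expect_equal(np$heights, sqrt(np$times), tolerance = 1e-12)
  flat <- structure(data.frame(times = t, heights = rep(0, 64),
                               speeds = rep(0, 64)),
                    class = c("rise_trace", "data.frame"))
  expect_error(normalize_trace(flat), class = "cuttleflow_invalid_input")
})

test_that("fit_rise_exponent recovers power laws and regime mixtures", {
  t <- seq(0, 10, length.out = 200)
  lin <- structure(data.frame(times = t, heights = 0.3 * t, speeds = rep(0.3, 200)),
                   class = c("rise_trace", "data.frame"))
  expect_equal(fit_rise_exponent(lin), 1, tolerance = 1e-10)
  sq <- structure(data.frame(times = t, heights = 0.3 * sqrt(t),
                             speeds = rep(0, 200)),
                  class = c("rise_trace", "data.frame"))
  expect_equal(fit_rise_exponent(sq), 0.5, tolerance = 1e-10)
  # a window straddling the crossover lies strictly between the regimes
  model <- washburn_model(water, gap_width = 1e-4)
  tau <- washburn_crossover_time(model)
  tr <- integrate_washburn(model, seq(0, 20 * tau, length.out = 400))
  expo <- fit_rise_exponent(tr, fit_range = c(0.001, 1))
  expect_gt(expo, 0.5)
  expect_lt(expo, 1.0)
  expect_error(fit_rise_exponent(lin, fit_range = c(0.9, 0.1)),
               class = "cuttleflow_invalid_parameter")
})

test_that("generate_rise_trace is seeded, noiseless-exact, and robust to noise", {
  model <- washburn_model(water, gap_width = 1e-4)
  tau <- washburn_crossover_time(model)
  times <- seq(0, 300 * tau, length.out = 300)
  clean <- generate_rise_trace(model, times, noise_sigma = 0)
  expect_equal(clean$heights, integrate_washburn(model, times)$heights)
  a <- generate_rise_trace(model, times, noise_sigma = 1e-4, seed = 9L)
  b <- generate_rise_trace(model, times, noise_sigma = 1e-4, seed = 9L)
  c <- generate_rise_trace(model, times, noise_sigma = 1e-4, seed = 10L)
  expect_identical(a$heights, b$heights)
  expect_false(identical(a$heights, c$heights))
  # 1% height noise in the late-time window still reads as Washburn
  zf <- clean$heights[300]
  noisy <- generate_rise_trace(model, times, noise_sigma = 0.01 * zf, seed = 4L)
  expect_equal(fit_rise_exponent(noisy, fit_range = c(0.5, 1)), 0.5,
               tolerance = 0.05)
})
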