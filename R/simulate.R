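#' Dual-channel geometry
#'
#' Geometry of one channel of a cuttlebone-inspired PDMS plate: a slit of
#' nominal width h0 running `total_length` with sinusoidally corrugated
#' ("wavy") walls of amplitude A, split into equally sized segments by
#' short gaps that mimic the non-continuous vertical pillars. The
#' experimental plates used 3.9 cm channels of 0.75 mm nominal width with
#' amplitudes of 0, 0.0625, 0.188 or 0.25 mm in three segments.
#'
#' @param total_length Channel length, m (default 39 mm).
#' @param nominal_width Nominal gap h0, m (default 0.75 mm).
#' @param amplitude Wall-corrugation amplitude A, m; must satisfy
#'   `0 <= A < h0/2`. See [amplitude_presets()].
#' @param wavelength Corrugation period, m (default 1.3 mm, about 30
#'   periods along the channel; not fixed by the experiments).
#' @param segment_count Number of equal segments (default 3).
#' @param segment_gap Length of the unconstricted gap between segments, m.
#' @param phase Corrugation phase offset, radians (relative wall phase of
#'   the two channels is a free parameter; default 0).
#' @return A `channel_geometry` object.
#' @export
channel_geometry <- function(total_length = 0.039, nominal_width = 0.75e-3,
                             amplitude = 0, wavelength = 1.3e-3,
                             segment_count = 3L, segment_gap = 1e-3,
                             phase = 0) {
  check_scalar(total_length, "total_length", lower = 0, strict_lower = TRUE)
  check_scalar(nominal_width, "nominal_width", lower = 0, strict_lower = TRUE)
  check_scalar(amplitude, "amplitude", lower = 0, upper = nominal_width / 2,
               strict_upper = TRUE)
  check_scalar(wavelength, "wavelength", lower = 0, strict_lower = TRUE)
  segment_count <- as.integer(segment_count)
  if (is.na(segment_count) || segment_count < 1L) {
    abort_invalid_parameter("`segment_count` must be a positive integer")
  }
  check_scalar(segment_gap, "segment_gap", lower = 0)
  if ((segment_count - 1L) * segment_gap >= total_length) {
    abort_invalid_parameter("segment gaps exceed the channel length")
  }
  check_scalar(phase, "phase")
  structure(
    list(total_length = total_length, nominal_width = nominal_width,
         amplitude = amplitude, wavelength = wavelength,
         segment_count = segment_count, segment_gap = segment_gap,
         phase = phase),
    class = "channel_geometry")
}

#' Wall-amplitude and head presets of the experimental plates
#'
#' @return Named numeric vectors in SI units (m).
#' @export
amplitude_presets <- function() {
  c(straight = 0, low = 0.0625e-3, mid = 0.188e-3, high = 0.25e-3)
}

#' @rdname amplitude_presets
#' @export
head_presets <- function() {
  c(low = 0.57e-2, mid = 1.14e-2, high = 1.33e-2)
}

#' Local channel width along the wall profile
#'
#' h(x) = h0 + A sin(2 pi x / wavelength + phase) within segments; inside
#' the inter-segment gaps the channel is unconstricted and the width is h0.
#'
#' @param geometry A [channel_geometry()].
#' @param position Position(s) along the channel, m, in
#'   `[0, total_length]`.
#' @return Local width(s), m.
#' @export
wall_profile <- function(geometry, position) {
  if (!inherits(geometry, "channel_geometry")) {
    abort_invalid_parameter("`geometry` must be a `channel_geometry`")
  }
  if (!is.numeric(position) || any(!is.finite(position))) {
    abort_invalid_parameter("`position` must be finite numeric")
  }
  if (any(position < 0 | position > geometry$total_length)) {
    abort_invalid_parameter("`position` outside [0, total_length]")
  }
  h <- geometry$nominal_width +
    geometry$amplitude * sin(2 * pi * position / geometry$wavelength +
                               geometry$phase)
  if (geometry$segment_count > 1L && geometry$segment_gap > 0) {
    seg_len <- (geometry$total_length -
                  (geometry$segment_count - 1L) * geometry$segment_gap) /
      geometry$segment_count
    pitch <- seg_len + geometry$segment_gap
    in_gap <- (position %% pitch) > seg_len & position < geometry$total_length
    h[in_gap] <- geometry$nominal_width
  }
  h
}

#' Simulation configuration
#'
#' Operating point and numerical settings of the stochastic dual-channel
#' simulator. `roughness_sigma` is the log-scale of the multiplicative
#' lognormal velocity noise (median 1) standing in for surface roughness
#' and minor channel-shape errors; it is redrawn once per output time step
#' and per channel.
#'
#' @param head_height Hydrostatic head ΔH, m (>= 0).
#' @param time_step Output sampling interval, s. The default `NULL`
#'   emulates choosing a recording frame rate per experiment: the interval
#'   is set to 1/230 of the expected traverse time of the run's head, so
#'   every condition yields roughly 150-300 local exponents.
#' @param duration Maximum simulated time, s; the run ends earlier once
#'   both fronts arrive.
#' @param roughness_sigma Lognormal log-scale of the velocity noise
#'   (default 0.1; 0 disables noise).
#' @param seed Integer RNG seed for the run.
#' @param resolution Pixel size for rendering and the separation floor, m.
#' @param l_ref Endpoint regularization length, m: the hydraulic length of
#'   the rectangular head the channels run into (default 14 mm), keeping
#'   the Darcy velocity finite at arrival.
#' @param initial_positions Length-2 starting front positions, m.
#' @param capillary_coupling Coefficient in `[0, 1]` on the wavy-wall
#'   modulation of the front capillary pressure,
#'   `2 sigma cos(theta) (1/h(S) - 1/h0)`. The default 0 reflects the
#'   pressure-budget argument that the static capillary jump is common to
#'   both menisci and contributes no differential driving; set > 0 to let
#'   constrictions pull the front harder.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(head_height, time_step = NULL, duration = 1.5,
                              roughness_sigma = 0.1, seed = 1L,
                              resolution = 2.5e-5, l_ref = 0.014,
                              initial_positions = c(0, 0),
                              capillary_coupling = 0) {
  check_scalar(head_height, "head_height", lower = 0)
  if (!is.null(time_step)) {
    check_scalar(time_step, "time_step", lower = 0, strict_lower = TRUE)
  }
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(roughness_sigma, "roughness_sigma", lower = 0)
  seed <- as.integer(seed)
  if (is.na(seed)) abort_invalid_parameter("`seed` must be an integer")
  check_scalar(resolution, "resolution", lower = 0, strict_lower = TRUE)
  check_scalar(l_ref, "l_ref", lower = 0, strict_lower = TRUE)
  if (!is.numeric(initial_positions) || length(initial_positions) != 2L ||
      any(initial_positions < 0)) {
    abort_invalid_parameter("`initial_positions` must be two non-negative values")
  }
  check_scalar(capillary_coupling, "capillary_coupling", lower = 0, upper = 1)
  structure(
    list(head_height = head_height, time_step = time_step,
         duration = duration, roughness_sigma = roughness_sigma,
         seed = seed, resolution = resolution, l_ref = l_ref,
         initial_positions = initial_positions,
         capillary_coupling = capillary_coupling),
    class = "simulation_config")
}

# run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Darcy front speed at position s in a channel: parallel-plate mobility
# h^2/(12 mu) times the driving gradient over the remaining air column.
# The static capillary jumps at the front and head menisci share the same
# nominal radius and cancel, so by default the driving is the hydrostatic
# head alone and waviness acts through the mobility h(s)^2. Optionally
# (cap_coupling > 0) the wavy-wall modulation of the front capillary
# pressure, 2 sigma cos(theta) (1/h(s) - 1/h0), is added: it sucks harder
# at constrictions and relaxes at bulges. Negative net driving clamps the
# front (it does not retreat).
darcy_speed <- function(s, geometry, fluid, head_pa, l_ref,
                        cap_coupling = 0) {
  h <- wall_profile(geometry, s)
  drive <- head_pa
  if (cap_coupling > 0) {
    drive <- drive + cap_coupling *
      2 * fluid$surface_tension * cos(fluid$contact_angle) *
      (1 / h - 1 / geometry$nominal_width)
  }
  h^2 / (12 * fluid$viscosity) * max(drive, 0) /
    (geometry$total_length - s + l_ref)
}

# expected traverse time of a straight noiseless channel under the pure
# head drive: ((L + L_ref)^2 - L_ref^2) / (2 k), k = h0^2 rho g dH/(12 mu)
estimate_traverse_time <- function(geometry, fluid, head, l_ref) {
  k <- geometry$nominal_width^2 / (12 * fluid$viscosity) *
    hydrostatic_pressure(fluid, head)
  if (k <= 0) return(Inf)
  ((geometry$total_length + l_ref)^2 - l_ref^2) / (2 * k)
}

#' Simulate a stochastic dual-channel filling run
#'
#' Advances the two front positions by explicit (midpoint) stepping of the
#' Darcy law
#'
#'   dS_i/dt = h_i(S_i)^2 / (12 mu) * P_i(S_i) / (L - S_i + L_ref) * xi_i(t)
#'
#' where h_i is the local wall profile, the driving pressure
#' `P_i = rho g ΔH + capillary_coupling * 2 sigma cos(theta) *
#' (1/h_i(S_i) - 1/h0)` defaults to the pure hydrostatic head (see
#' [simulation_config()]), L_ref regularizes the vanishing air column at
#' arrival, and xi_i is i.i.d. lognormal noise with median 1 and log-scale
#' `roughness_sigma`, redrawn per output step and channel.
#' The 1/(L - S) dependence means a leading front sees a shorter air
#' column and accelerates — the feedback that amplifies any initial lead
#' into exponential separation. Internally each output step is subdivided
#' so no substep advances a front by more than wavelength/20, resolving
#' the wall corrugation; fronts are clamped at L and the run ends once
#' both arrive.
#'
#' @param geometry1,geometry2 [channel_geometry()] objects sharing
#'   `total_length`.
#' @param fluid A [fluid_properties()] object.
#' @param config A [simulation_config()].
#' @return A [dual_trace()] with `head` and `amplitude` metadata filled
#'   from the configuration and `geometry1`.
#' @examples
#' g <- channel_geometry(amplitude = 0.188e-3)
#' cfg <- simulation_config(head_height = 1.33e-2, seed = 42)
#' tr <- simulate_dual_channel(g, g, fluid_properties(), cfg)
#' @export
simulate_dual_channel <- function(geometry1, geometry2, fluid, config) {
  for (g in list(geometry1, geometry2)) {
    if (!inherits(g, "channel_geometry")) {
      abort_invalid_parameter("geometries must be `channel_geometry` objects")
    }
  }
  if (geometry1$total_length != geometry2$total_length) {
    abort_invalid_parameter("the two geometries must share `total_length`")
  }
  assert_fluid(fluid)
  if (!inherits(config, "simulation_config")) {
    abort_invalid_parameter("`config` must be a `simulation_config`")
  }
  L <- geometry1$total_length
  head_pa <- hydrostatic_pressure(fluid, config$head_height)
  geoms <- list(geometry1, geometry2)
  ds_max <- min(geometry1$wavelength, geometry2$wavelength) / 20
  dt <- config$time_step
  if (is.null(dt)) {
    t_est <- estimate_traverse_time(geometry1, fluid, config$head_height,
                                    config$l_ref)
    dt <- if (is.finite(t_est)) t_est / 230 else 5e-4
  }
  n_max <- ceiling(config$duration / dt) + 1L
  s <- pmin(config$initial_positions, L)
  S <- matrix(NA_real_, nrow = n_max, ncol = 2L)
  S[1L, ] <- s
  n_used <- n_max
  with_seed(config$seed, {
    for (k in 2:n_max) {
      xi <- if (config$roughness_sigma > 0) {
        stats::rlnorm(2L, meanlog = 0, sdlog = config$roughness_sigma)
      } else c(1, 1)
      for (i in 1:2) {
        si <- s[i]
        t_in <- 0
        while (t_in < dt && si < L) {
          v <- darcy_speed(si, geoms[[i]], fluid, head_pa, config$l_ref,
                           config$capillary_coupling %||% 0) * xi[i]
          if (!is.finite(v) || v < 0) {
            abort_numerical_failure("non-finite or negative front speed")
          }
          if (v == 0) break
          dt_sub <- min(dt - t_in, ds_max / v)
          # explicit midpoint step: second-order in the substep length
          s_half <- min(si + 0.5 * v * dt_sub, L)
          v_mid <- darcy_speed(s_half, geoms[[i]], fluid, head_pa,
                               config$l_ref,
                               config$capillary_coupling %||% 0) * xi[i]
          si <- min(si + v_mid * dt_sub, L)
          t_in <- t_in + dt_sub
        }
        s[i] <- si
      }
      S[k, ] <- s
      if (all(s >= L)) { n_used <- k; break }
    }
  })
  n_used <- min(n_used, n_max)
  if (n_used < 8L) {
    # very fast runs: pad with the arrived state so the trace is well-formed
    S[(n_used + 1L):8L, ] <- rep(S[n_used, ], each = 8L - n_used)
    n_used <- 8L
  }
  idx <- seq_len(n_used)
  dual_trace(times = (idx - 1L) * dt, s1 = S[idx, 1L], s2 = S[idx, 2L],
             head = config$head_height, amplitude = geometry1$amplitude,
             label = sprintf("sim seed=%d dH=%gm A=%gm", config$seed,
                             config$head_height, geometry1$amplitude))
}

#' Stable per-run seed derived from a condition tuple
#'
#' Folds the base seed and the condition tuple (head, amplitude, replicate)
#' through a 31-multiplier polynomial hash of the formatted tuple, modulo
#' the Mersenne prime 2^31 - 1. Deterministic across platforms, so an
#' ensemble is exactly reproducible from its base seed and grid.
#'
#' @param base_seed Integer base seed.
#' @param head,amplitude Condition values, m.
#' @param replicate Replicate index (1-based).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, head, amplitude, replicate) {
  key <- sprintf("%.9g|%.9g|%d", head, amplitude, as.integer(replicate))
  h <- as.double(base_seed) %% 2147483647
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

#' Simulate an ensemble over heads, amplitudes and replicates
#'
#' Runs [simulate_dual_channel()] followed by the separation ->
#' local-log-slope -> upper-quantile chain for every cell of the
#' head x amplitude x replicate grid. Per-run seeds come from
#' [derive_seed()], so the whole table is reproducible from
#' `base_config$seed`. A failed cell is recorded with `ok = FALSE` rather
#' than aborting the ensemble.
#'
#' @param fluid A [fluid_properties()].
#' @param heads Numeric vector of hydrostatic heads, m.
#' @param amplitudes Numeric vector of wall amplitudes, m.
#' @param n_seeds Replicates per cell (>= 1).
#' @param base_config A [simulation_config()] providing everything except
#'   `head_height` and `seed` (its values for those are ignored).
#' @param geometry Template [channel_geometry()]; each cell replaces its
#'   `amplitude`. Both channels use the same geometry.
#' @param window,degree,quantile Passed to the analysis chain.
#' @param floor Separation floor, m; defaults to `base_config$resolution`.
#' @return A data frame with one row per run: `head_m`, `amplitude_m`,
#'   `replicate`, `seed`, `lambda_q`, `n_exponents`, `crossings`, `ok`.
#' @export
simulate_ensemble <- function(fluid, heads, amplitudes, n_seeds, base_config,
                              geometry = channel_geometry(),
                              window = 7L, degree = 4L, quantile = 0.75,
                              floor = NULL) {
  if (!is.numeric(heads) || length(heads) < 1L ||
      !is.numeric(amplitudes) || length(amplitudes) < 1L) {
    abort_invalid_parameter("`heads` and `amplitudes` must be non-empty numeric")
  }
  n_seeds <- as.integer(n_seeds)
  if (is.na(n_seeds) || n_seeds < 1L) {
    abort_invalid_parameter("`n_seeds` must be >= 1")
  }
  if (is.null(floor)) floor <- base_config$resolution
  grid <- expand.grid(replicate = seq_len(n_seeds), amplitude = amplitudes,
                      head = heads, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(j) {
    hd <- grid$head[j]; am <- grid$amplitude[j]; rep_i <- grid$replicate[j]
    seed_j <- derive_seed(base_config$seed, hd, am, rep_i)
    cfg <- base_config
    cfg$head_height <- hd
    cfg$seed <- seed_j
    geom <- geometry
    geom$amplitude <- am
    out <- tryCatch({
      tr <- simulate_dual_channel(geom, geom, fluid, cfg)
      ser <- separation(tr, floor = floor)
      lam <- local_log_slope(ser, window = window, degree = degree)
      summ <- percentile_summary(lam, quantile = quantile)
      data.frame(head_m = hd, amplitude_m = am, replicate = rep_i,
                 seed = seed_j, lambda_q = summ$lambda_q,
                 n_exponents = summ$n_exponents,
                 crossings = crossing_count(tr, floor = floor), ok = TRUE)
    }, error = function(e) {
      data.frame(head_m = hd, amplitude_m = am, replicate = rep_i,
                 seed = seed_j, lambda_q = NA_real_,
                 n_exponents = NA_integer_, crossings = NA_integer_,
                 ok = FALSE)
    })
    out
  })
  do.call(rbind, rows)
}

#' Generate a noisy capillary-rise trace
#'
#' Integrates a [washburn_model()] and adds i.i.d. Gaussian height noise
#' (clipped at zero), as a stand-in for digitized penetration-length
#' measurements.
#'
#' @param model A [washburn_model()].
#' @param times Output time grid, s (starting at 0, strictly increasing).
#' @param noise_sigma Additive height-noise standard deviation, m (>= 0).
#' @param seed Integer RNG seed.
#' @return A `rise_trace`; with `noise_sigma = 0` it is identical to the
#'   [integrate_washburn()] output.
#' @export
generate_rise_trace <- function(model, times, noise_sigma = 0, seed = 1L) {
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  trace <- integrate_washburn(model, times)
  if (noise_sigma > 0) {
    noisy <- with_seed(seed, {
      pmax(trace$heights + stats::rnorm(nrow(trace), sd = noise_sigma), 0)
    })
    trace <- new_rise_trace(trace$times, noisy, trace$speeds)
  }
  trace
}
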