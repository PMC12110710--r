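# Fixtures built in code: hand-crafted trajectory/profile objects for unit
# tests that need exactly known dwell times.

# A fake recorded trajectory moving on a circle of radius r0 with uniform
# time spacing; total duration (n_steps) * dt.
circle_trajectory <- function(r0, n_steps = 100L, dt = 0.01, radius = 1) {
  t <- seq(0, n_steps * dt, by = dt)
  phi <- seq(0, 2 * pi, length.out = length(t))
  structure(data.frame(t = t, x = r0 * cos(phi), y = r0 * sin(phi),
                       theta = phi + pi / 2, state = 1L),
            class = c("search_trajectory", "data.frame"),
            escape_time = n_steps * dt, absorbed = FALSE,
            contour_step = NA_real_, domain = disk_domain(radius))
}

# An occupancy profile with prescribed densities (dwell = density * area).
profile_with_density <- function(density, radius = 1) {
  b <- radial_binning(radius, length(density))
  disksearch:::new_occupancy_profile(density * b$area, b,
                                     n_trajectories = 1L, n_absorbed = 1L,
                                     n_censored = 0L, mean_time = NA_real_,
                                     mean_escape_time = NA_real_)
}

baseline_policy <- function() switch_policy("constant", motility_params(1, 2))

two_state_policy <- function(mode = c("rate", "positional")) {
  mode <- match.arg(mode)
  s1 <- motility_params(1, 0.67)
  s2 <- motility_params(1, 6.0)
  if (mode == "rate") switch_policy("rate", s1, s2, k = 2.0)
  else switch_policy("positional", s1, s2, r_switch = 0.5)
}

# One long free path (huge disk, never absorbed) for correlation analysis.
long_free_path <- function(d_theta, t_max = 2000, seed = 7,
                           stride = 5L) {
  cfg <- sim_config(dt = 1e-3, t_max = t_max, seed = seed,
                    record_stride = stride)
  suppressWarnings(simulate_trajectory(
    cfg, switch_policy("constant", motility_params(1, d_theta)),
    disk_domain(1e6)))
}
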