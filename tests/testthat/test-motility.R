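test_that("advance_step implements the constant-speed Euler update", {
  p <- motility_params(1, 0)
  s <- advance_step(0, 0, 0, p, dt = 1e-3, noise = 1.7)
  expect_equal(s$x, 1e-3)
  expect_equal(s$y, 0)
  expect_equal(s$theta, 0)  # zero angular diffusion: heading frozen

  s <- advance_step(0, 0, pi / 2, motility_params(1, 2), dt = 1e-3,
                    noise = 0)
  expect_equal(s$x, 0, tolerance = 1e-12)
  expect_equal(s$y, 1e-3)
  expect_equal(s$theta, pi / 2)  # zero deviate: heading unchanged

  # step length is exactly v0*dt whatever the heading
  th <- seq(0, 2 * pi, length.out = 17)
  s <- advance_step(rep(0, 17), rep(0, 17), th, motility_params(0.8, 3),
                    dt = 0.01, noise = stats::rnorm(17))
  expect_equal(sqrt(s$x^2 + s$y^2), rep(0.8 * 0.01, 17))

  expect_error(advance_step(NaN, 0, 0, p, 1e-3, 0), "finite")
  expect_error(advance_step(0, 0, 0, p, 1e-3, Inf), "finite")
})

test_that("heading increments have variance 2*D_theta*dt", {
  set.seed(42)
  noise <- stats::rnorm(1e6)
  s <- advance_step(0, 0, 0, motility_params(1, 2), dt = 1e-3, noise = noise)
  v <- stats::var(s$theta)
  expect_lt(abs(v - 0.004) / 0.004, 0.01)
})

test_that("ballistic limit crosses the radius in exactly R/v0", {
  cfg <- sim_config(dt = 1e-3, seed = 3)
  tr <- simulate_trajectory(cfg, switch_policy("constant",
                                               motility_params(1, 0)))
  expect_true(attr(tr, "absorbed"))
  expect_equal(attr(tr, "escape_time"), 1.0, tolerance = 1e-12)
  # recorded path: every position but the last strictly inside the disk
  r <- sqrt(tr$x^2 + tr$y^2)
  expect_true(all(r[-length(r)] < 1))
  expect_gte(r[length(r)], 1)
})

test_that("recorded steps at stride 1 have length exactly v0*dt", {
  cfg <- sim_config(dt = 1e-3, seed = 5, record_stride = 1L)
  tr <- simulate_trajectory(cfg, baseline_policy())
  step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  expect_equal(step, rep(1e-3, length(step)), tolerance = 1e-12)
  expect_equal(diff(tr$t), rep(1e-3, length(step)), tolerance = 1e-12)
})

test_that("ensembles are deterministic and substream-reproducible", {
  cfg <- sim_config(n_trajectories = 40, seed = 9)
  e1 <- simulate_ensemble(cfg, two_state_policy("rate"))
  e2 <- simulate_ensemble(cfg, two_state_policy("rate"))
  expect_identical(e1$escape_time, e2$escape_time)
  expect_identical(e1$dwell, e2$dwell)
  # trajectory i of the ensemble is reproduced by its own substream
  tr <- simulate_trajectory(cfg, two_state_policy("rate"), traj_index = 17L)
  expect_identical(attr(tr, "escape_time"), e1$escape_time[17])
  expect_identical(attr(tr, "switch_time"),
                   if (e1$switched[17]) e1$switch_time[17] else NA_real_)
})

test_that("exponential switching times have the right moments", {
  expect_error(draw_switch_time(0), "> 0")
  expect_error(draw_switch_time(-1), "> 0")
  set.seed(7)
  w <- draw_switch_time(2.0, n = 1e5)
  expect_lt(abs(mean(w) - 0.5) / 0.5, 0.02)
  expect_lt(abs(stats::median(w) - log(2) / 2) / (log(2) / 2), 0.02)
})

test_that("rate-mode switch occurs on average at r = v0/k for straight runs", {
  # ballistic first state on a large disk: switch radius equals the
  # exponential waiting time, mean 1/k = 0.5
  pol <- switch_policy("rate", motility_params(1, 0), motility_params(1, 6),
                       k = 2.0)
  cfg <- sim_config(n_trajectories = 10000, seed = 5, t_max = 5)
  ens <- suppressWarnings(simulate_ensemble(cfg, pol, disk_domain(10)))
  r_sw <- ens$switch_radius[ens$switched]
  expect_lt(abs(mean(r_sw) - 0.5) / 0.5, 0.02)
})

test_that("positional switching triggers within one step of the radius", {
  pol <- two_state_policy("positional")
  cfg <- sim_config(n_trajectories = 200, seed = 13)
  ens <- simulate_ensemble(cfg, pol)
  r_sw <- ens$switch_radius[ens$switched]
  expect_true(all(r_sw >= 0.5 & r_sw <= 0.5 + 1e-3))
  # state flags never decrease along a recorded path
  tr <- simulate_trajectory(cfg, pol, traj_index = 2L)
  expect_true(all(diff(tr$state) >= 0))
})

test_that("slow searchers are censored with a warning, not an error", {
  cfg <- sim_config(n_trajectories = 5, seed = 2, t_max = 0.1)
  pol <- switch_policy("constant", motility_params(0.01, 5))
  expect_warning(ens <- simulate_ensemble(cfg, pol), "censored")
  expect_equal(ens$n_censored, 5L)
  expect_true(all(!ens$absorbed))
  expect_equal(ens$escape_time, rep(0.1, 5))
  expect_error(mean_escape_time(ens), "censored")
})

test_that("per-step Bernoulli switching approximates the exponential law", {
  pol <- switch_policy("rate", motility_params(1, 0), motility_params(1, 6),
                       k = 2.0, rate_method = "bernoulli")
  cfg <- sim_config(n_trajectories = 4000, seed = 21, t_max = 5)
  ens <- suppressWarnings(simulate_ensemble(cfg, pol, disk_domain(10)))
  expect_lt(abs(mean(ens$switch_time[ens$switched]) - 0.5) / 0.5, 0.05)
})

test_that("small-persistence-length walks escape like pure diffusion", {
  # lp = 0.02: mean exit time should approach R^2/(4D) with D = v0^2/(2 Dth)
  p <- motility_params(1, 50)
  ens <- simulate_ensemble(sim_config(n_trajectories = 400, seed = 31),
                           switch_policy("constant", p))
  tesc <- ens$escape_time[ens$absorbed]
  theory <- mean_exit_time_disk(diffusion_model(effective_diffusion(p), 1))
  se <- stats::sd(tesc) / sqrt(length(tesc))
  expect_lt(abs(mean(tesc) - theory), 4 * se + 0.02 * theory)
})

test_that("invalid configurations are rejected by name", {
  expect_error(motility_params(-1, 2), "v0")
  expect_error(motility_params(1, -2), "d_theta")
  expect_error(switch_policy("rate", motility_params(1, 1),
                             motility_params(1, 2)), "k")
  expect_error(switch_policy("positional", motility_params(1, 1),
                             motility_params(1, 2)), "r_switch")
  expect_error(sim_config(dt = 0), "dt")
  pol <- switch_policy("positional", motility_params(1, 1),
                       motility_params(1, 2), r_switch = 2)
  expect_error(simulate_ensemble(sim_config(n_trajectories = 2), pol,
                                 disk_domain(1)), "r_switch")
})
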