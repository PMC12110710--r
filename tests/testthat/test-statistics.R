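test_that("radial binning tiles the disk", {
  b <- radial_binning(1, 20)
  expect_length(b$edges, 21L)
  expect_true(all(diff(b$edges) > 0))
  expect_true(all(b$area > 0))
  expect_equal(sum(b$area), pi, tolerance = 1e-12)
  b2 <- radial_binning(2.5, 7)
  expect_equal(sum(b2$area), pi * 2.5^2, tolerance = 1e-12)
})

test_that("a path confined to one annulus puts all dwell time there", {
  tr <- circle_trajectory(r0 = 0.575, n_steps = 200L, dt = 0.01)
  prof <- bin_occupancy(tr, radial_binning(1, 20))
  expect_equal(prof$dwell_time[12], 2.0)   # region (0.55, 0.60]: 200 * 0.01
  expect_equal(sum(prof$dwell_time[-12]), 0)
  expect_equal(prof$density[12], 2.0 / prof$area[12])
})

test_that("dwell time is conserved: regions sum to the mean search time", {
  ens <- simulate_ensemble(sim_config(n_trajectories = 300, seed = 17),
                           baseline_policy())
  prof <- bin_occupancy(ens)
  expect_equal(sum(prof$dwell_time), mean(ens$escape_time),
               tolerance = 1e-9)
})

test_that("positions outside the disk are rejected as inconsistent", {
  tr <- circle_trajectory(r0 = 1.2, n_steps = 10L, radius = 1)
  expect_error(bin_occupancy(tr, radial_binning(1, 20)), "inconsistent")
  expect_error(bin_occupancy(list(), radial_binning(1, 20)), "empty")
})

test_that("coverage uniformity is the relative spread of region densities", {
  prof <- profile_with_density(rep(3.7, 20))
  s <- coverage_uniformity(prof)
  expect_equal(s$relative_std, 0)
  prof2 <- profile_with_density(c(rep(1, 10), rep(3, 10)))
  s2 <- coverage_uniformity(prof2)
  expect_equal(s2$density_mean, 2)
  expect_equal(s2$relative_std, stats::sd(c(rep(1, 10), rep(3, 10))) / 2)
  expect_error(coverage_uniformity(profile_with_density(rep(0, 20))),
               "undefined")
})

test_that("tangent correlation is exact for degenerate paths", {
  tr <- long_free_path(0, t_max = 50, stride = 10L)  # straight
  fit <- tangent_correlation(tr, lags = c(0, 0.1, 1, 5))
  expect_equal(fit$correlation, rep(1, 4))
  expect_error(tangent_correlation(tr, lags = 40), "insufficient")
})

test_that("tangent correlation decays as exp(-D_theta * l / v0)", {
  tr <- long_free_path(2, t_max = 3000, seed = 3)
  fit <- tangent_correlation(tr, lags = 0.5)
  expect_lt(abs(fit$correlation - exp(-1)), 0.03)
  # overlapping windows estimate the same quantity
  fit_o <- tangent_correlation(tr, lags = 0.5, overlapping = TRUE)
  expect_lt(abs(fit_o$correlation - exp(-1)), 0.03)
})

test_that("persistence-length fit inverts an exact exponential", {
  ell <- seq(0, 2, by = 0.05)
  fit <- structure(data.frame(ell = ell, correlation = exp(-ell / 0.5),
                              n_pairs = 100L),
                   class = c("persistence_fit", "data.frame"))
  expect_equal(as.numeric(estimate_persistence_length(fit)), 0.5,
               tolerance = 1e-10)
  # a non-decaying correlation only bounds lp from below
  flat <- structure(data.frame(ell = ell, correlation = rep(1, length(ell)),
                               n_pairs = 100L),
                    class = c("persistence_fit", "data.frame"))
  lp <- estimate_persistence_length(flat)
  expect_true(is.infinite(lp))
  expect_equal(attr(lp, "lower_bound"), 2)
  short <- structure(data.frame(ell = c(0, 1), correlation = c(1, 0.5),
                                n_pairs = 10L),
                     class = c("persistence_fit", "data.frame"))
  expect_error(estimate_persistence_length(short), "3 usable lags")
})

test_that("persistence length is recovered from simulated paths", {
  tr <- long_free_path(2, t_max = 2000, seed = 11)
  lp <- estimate_persistence_length(tangent_correlation(tr))
  expect_lt(abs(lp - 0.5) / 0.5, 0.1)
})

test_that("freely-jointed-chain algebra and sampling agree", {
  f <- fjc_relations(1, 0.3)
  expect_equal(f$L, 0.3)
  expect_equal(f$S2, 0.09)
  f2 <- fjc_relations(1000, 0.01)
  expect_equal(f2$L, 10)
  expect_equal(f2$S2, 0.1)
  set.seed(29)
  s2 <- simulate_fjc(1e4, 1000, 0.01)
  se <- stats::sd(s2) / sqrt(length(s2))
  expect_lt(abs(mean(s2) - 0.1), 3 * se)
})

test_that("two-state parameters: Kuhn ratio 1/9 and geometric-mean baseline", {
  s1 <- motility_params(1, 0.67)
  s2 <- motility_params(1, 6.0)
  expect_equal(kuhn_length(s2) / kuhn_length(s1), 0.67 / 6.0)
  # the constant-protocol D_theta = 2.0 is the geometric mean of the
  # two-state values to within 1%
  expect_lt(abs(sqrt(0.67 * 6.0) - 2.0) / 2.0, 0.01)
})

test_that("outer-slope fit recovers an exact line and validates input", {
  b <- radial_binning(1, 20)
  prof <- profile_with_density(10 - 5 * b$midpoint)
  sl <- fit_outer_slope(prof)
  expect_equal(as.numeric(sl), 5, tolerance = 1e-10)
  expect_equal(attr(sl, "slope"), -5, tolerance = 1e-10)
  expect_error(fit_outer_slope(prof, n_outer = 1L), "at least 2")
})
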