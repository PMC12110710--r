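test_that("effective diffusion follows D = v0^2/(2 D_theta)", {
  expect_equal(effective_diffusion(motility_params(1, 200)), 2.5e-3)
  expect_equal(effective_diffusion(motility_params(1, 2)), 0.25)
  expect_equal(effective_diffusion(motility_params(0, 3)), 0)
  expect_error(effective_diffusion(motility_params(1, 0)), "infinite")
})

test_that("the free-space Gaussian is normalised with rms radius sqrt(4Dt)", {
  D <- 0.25
  for (t in c(0.3, 1, 7)) {
    norm <- stats::integrate(function(r) free_space_profile(r, t, D) *
                               2 * pi * r, 0, Inf)$value
    expect_equal(norm, 1, tolerance = 1e-6)
    msd <- stats::integrate(function(r) r^2 * free_space_profile(r, t, D) *
                              2 * pi * r, 0, Inf)$value
    expect_equal(sqrt(msd), sqrt(4 * D * t), tolerance = 1e-6)
  }
  expect_equal(free_space_profile(0, 1, 0.25), 1 / pi)
  expect_error(free_space_profile(1, 0, 0.25), "> 0")
})

test_that("free drift speed is 2D/r and implies uniform coverage", {
  expect_equal(drift_speed_free(1, 0.25), 0.5)
  expect_equal(drift_speed_free(2, 0.25), 0.25)  # doubling r halves v
  expect_error(drift_speed_free(0, 0.25), "r = 0")
  expect_equal(uniform_coverage_density(0.25), 1 / pi)
})

test_that("rim drift speed D/(R-r) is independent of the density slope", {
  m <- diffusion_model(2.5e-3, 1)
  expect_equal(drift_speed_rim(0, m), 2.5e-3)
  v <- drift_speed_rim(seq(0, 0.99, by = 0.01), m)
  expect_true(all(diff(v) > 0))  # diverges monotonically toward the rim
  expect_error(drift_speed_rim(1, m), "diverges")
  # J/P with P = gamma*(R-r), J = D*gamma reproduces v for any gamma
  for (gam in c(0.1, 1, 50)) {
    r <- c(0.5, 0.9, 0.99)
    expect_equal((m$D * gam) / (gam * (1 - r)), drift_speed_rim(r, m))
  }
})

test_that("near-rim occupancy vanishes at the rim with slope 1/(2 pi D R)", {
  m <- diffusion_model(2.5e-3, 1)
  expect_equal(rim_occupancy(1, m), 0)
  expect_equal(rim_occupancy(0.5, m), 0.5 / (2 * pi * 2.5e-3 * 0.5))
  expect_equal(rim_slope(m), 1 / (2 * pi * 2.5e-3), tolerance = 1e-12)
  expect_error(rim_occupancy(0, m), "r = 0")
})

test_that("the exact occupancy integrates to the mean exit time", {
  m <- diffusion_model(2.5e-3, 1)
  expect_equal(greens_occupancy(1, m), 0)
  tot <- stats::integrate(function(r) greens_occupancy(r, m) * 2 * pi * r,
                          0, 1, rel.tol = 1e-10)$value
  expect_equal(tot, 100, tolerance = 1e-6)
  expect_equal(mean_exit_time_disk(m), 100)
  # bin-averaged occupancy conserves the same integral, central bin included
  b <- radial_binning(1, 20)
  gb <- greens_occupancy_binned(b, m)
  expect_equal(sum(gb * b$area), 100, tolerance = 1e-10)
})

test_that("exact and near-rim occupancy agree to first order at the rim", {
  m <- diffusion_model(2.5e-3, 1)
  r <- seq(0.965, 0.995, by = 0.005)
  rel <- abs(greens_occupancy(r, m) - rim_occupancy(r, m)) /
    rim_occupancy(r, m)
  expect_lt(max(rel), 0.02)
  # the relative deviation is (1 - r)/2 to leading order
  expect_equal(rel, (1 - r) / 2, tolerance = 0.02)
})

test_that("the finite-volume solver reproduces the exact occupancy", {
  m <- diffusion_model(2.5e-3, 1)
  sol <- solve_radial_fpe(m)
  expect_true(all(diff(sol$survival) <= 1e-12))   # absorbing boundary
  expect_lt(sol$survival[length(sol$survival)], 1e-6)
  expect_equal(sol$mean_exit_time, 100, tolerance = 0.02)
  g <- greens_occupancy(sol$r, m)
  sel <- sol$r > 0.1
  expect_lt(max(abs(sol$occupancy[sel] - g[sel]) / g[sel]), 0.02)
})

test_that("solver occupancy converges under grid refinement", {
  m <- diffusion_model(0.01, 1)
  dev_for <- function(n) {
    sol <- solve_radial_fpe(m, radial_grid(1, n))
    sel <- sol$r > 0.1
    max(abs(sol$occupancy[sel] - greens_occupancy(sol$r[sel], m)) /
          greens_occupancy(sol$r[sel], m))
  }
  expect_lt(dev_for(200), dev_for(50))
})

test_that("the image-charge construction fails at the rim", {
  m <- diffusion_model(2.5e-3, 1)
  ts <- c(20, 50, 100, 200)
  res <- image_method_residual(ts, m)
  # the residual P(R,t) + Pbar(R,t) is appreciable, not a numerical zero
  expect_true(all(res > 0))
  direct <- vapply(ts, function(t) free_space_profile(1, t, m$D), 0)
  expect_gt(max(res / direct), 0.5)
})
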