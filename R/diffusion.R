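#' Coarse-grained diffusion coefficient of the active walk
#'
#' On scales far beyond its persistence length, the constant-speed walk
#' with angular diffusion behaves as ordinary 2D diffusion with
#' `D = v0^2 / (2 * d_theta)`.
#'
#' @param params [motility_params()] with `d_theta > 0`.
#' @return The translational diffusion coefficient `D`.
#' @examples
#' effective_diffusion(motility_params(1, 200))  # 2.5e-3
#' @export
effective_diffusion <- function(params) {
  stopifnot(inherits(params, "motility_params"))
  if (params$d_theta == 0)
    stop("d_theta = 0: the effective diffusion coefficient is infinite",
         call. = FALSE)
  params$v0^2 / (2 * params$d_theta)
}

#' Free-space spreading Gaussian
#'
#' Radial probability density (per unit area) of 2D diffusion released at
#' the origin at `t = 0` on an unbounded plane:
#' `P(r, t) = exp(-r^2 / (4 D t)) / (4 pi D t)`.
#'
#' @param r Radius (vectorised).
#' @param t Time, `> 0`.
#' @param D Diffusion coefficient.
#' @return Density values.
#' @export
free_space_profile <- function(r, t, D) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0)
    stop("`t` must be a finite time > 0", call. = FALSE)
  stopifnot(is.numeric(D), D > 0, all(r >= 0))
  exp(-r^2 / (4 * D * t)) / (4 * pi * D * t)
}

#' Outward drift speed of free 2D diffusion
#'
#' The root-mean-square distance of free diffusion grows as
#' `sqrt(4 D t)`, equivalent to an effective outward drift `v = 2 D / r`.
#'
#' @param r Radius, `> 0` (vectorised).
#' @param D Diffusion coefficient.
#' @return Drift speed `2 D / r`.
#' @export
drift_speed_free <- function(r, D) {
  stopifnot(is.numeric(D), D > 0)
  if (any(r == 0)) stop("drift speed diverges at r = 0", call. = FALSE)
  2 * D / r
}

#' Uniform coverage density of unbounded diffusion
#'
#' A drift proportional to `1/r` spends time per area `1/(4*pi*D)` in every
#' annulus: unbounded diffusion covers the plane uniformly.
#'
#' @param D Diffusion coefficient.
#' @return `1 / (4 * pi * D)`.
#' @export
uniform_coverage_density <- function(D) {
  stopifnot(is.numeric(D), D > 0)
  1 / (4 * pi * D)
}

#' Drift speed toward an absorbing rim
#'
#' Near an absorbing boundary the density is approximately linear,
#' `P = gamma * (R - r)`, and the flux is `D * gamma`; their ratio gives a
#' drift speed `v = D / (R - r)` independent of the slope `gamma`.
#'
#' @param r Radius, `0 <= r < R` (vectorised).
#' @param model [diffusion_model()].
#' @return Drift speed `D / (R - r)`.
#' @export
drift_speed_rim <- function(r, model) {
  stopifnot(inherits(model, "diffusion_model"))
  if (any(r >= model$radius))
    stop("drift speed diverges at r >= R", call. = FALSE)
  model$D / (model$radius - r)
}

#' Near-rim dwell-time density
#'
#' With drift `D/(R - r)` toward the rim, the search time per unit area in
#' an annulus at radius `r` is `(R - r) / (2 * pi * D * r)`: it vanishes
#' linearly at the absorbing rim.
#'
#' @param r Radius, `0 < r <= R` (vectorised).
#' @param model [diffusion_model()].
#' @return Dwell-time density.
#' @export
rim_occupancy <- function(r, model) {
  stopifnot(inherits(model, "diffusion_model"))
  if (any(r == 0)) stop("rim occupancy diverges at r = 0", call. = FALSE)
  (model$radius - r) / (2 * pi * model$D * r)
}

#' Theoretical slope of the dwell-time density at the rim
#'
#' Magnitude of the derivative of [rim_occupancy()] at \eqn{r = R}:
#' `1 / (2 * pi * D * R)`.  This is the closed-form value against which the
#' fitted outer-annulus slope of a diffusive-limit simulation is compared.
#'
#' @param model [diffusion_model()].
#' @return Slope magnitude.
#' @examples
#' rim_slope(diffusion_model(2.5e-3))  # 63.66
#' @export
rim_slope <- function(model) {
  stopifnot(inherits(model, "diffusion_model"))
  1 / (2 * pi * model$D * model$radius)
}

#' Exact expected occupancy of diffusion from the disk center
#'
#' For pure diffusion released at the center of a disk with absorbing rim,
#' the expected total time spent per unit area at radius `r` before
#' absorption is `u(r) = log(R / r) / (2 * pi * D)`.  Its integral over the
#' disk is the mean exit time `R^2 / (4 D)`, and near the rim it reduces to
#' [rim_occupancy()] to first order in `R - r`.  Serves as the analytic
#' oracle for both the simulator (small persistence length) and the
#' finite-volume solver.
#'
#' @param r Radius, `0 < r <= R` (vectorised).
#' @param model [diffusion_model()].
#' @return Occupancy density `u(r)`.
#' @export
greens_occupancy <- function(r, model) {
  stopifnot(inherits(model, "diffusion_model"))
  if (any(r == 0)) stop("occupancy density diverges (logarithmically) at ",
                        "r = 0; use greens_occupancy_binned()", call. = FALSE)
  log(model$radius / r) / (2 * pi * model$D)
}

#' Bin-averaged exact occupancy
#'
#' Average of [greens_occupancy()] over each region of a radial binning
#' (closed form, valid for the central region despite the logarithmic
#' singularity at \eqn{r = 0}).
#'
#' @param binning [radial_binning()].
#' @param model [diffusion_model()].
#' @return Numeric vector: expected dwell-time density per region.
#' @export
greens_occupancy_binned <- function(binning, model) {
  stopifnot(inherits(binning, "radial_binning"),
            inherits(model, "diffusion_model"))
  R <- model$radius
  # int u * 2*pi*r dr = [ r^2/2 * log(R/r) + r^2/4 ] / D   (limit 0 at r=0)
  antider <- function(r) ifelse(r == 0, 0,
                                (r^2 / 2 * log(R / r) + r^2 / 4) / model$D)
  e <- binning$edges
  (antider(e[-1]) - antider(e[-length(e)])) / binning$area
}

#' Mean exit time of diffusion from the disk center
#'
#' @param model [diffusion_model()].
#' @return `R^2 / (4 D)`.
#' @export
mean_exit_time_disk <- function(model) {
  stopifnot(inherits(model, "diffusion_model"))
  model$radius^2 / (4 * model$D)
}

#' Residual of the image-charge construction at the rim
#'
#' Placing a negative image source at \eqn{r = 2R} does not enforce the
#' absorbing condition on the disk: the evolved image density
#' `-I0(rR/(Dt)) * exp(-(r^2 + 4R^2)/(4Dt)) / (4 pi D t)` fails to cancel
#' the direct spreading Gaussian at \eqn{r = R} at all times.  This function
#' returns that non-zero residual `P(R,t) + Pbar(R,t)` — a demonstration
#' that the radial problem has no simple image solution, not a usable
#' boundary construction.
#'
#' @param t Time, `> 0` (vectorised).
#' @param model [diffusion_model()].
#' @return Residual density at the rim.
#' @export
image_method_residual <- function(t, model) {
  stopifnot(inherits(model, "diffusion_model"), all(t > 0))
  D <- model$D
  R <- model$radius
  z <- R^2 / (D * t)
  # P(R,t) + Pbar(R,t), written with the exponentially scaled Bessel I0
  # to avoid overflow: both terms share the factor exp(-R^2/(4Dt)).
  (1 / (4 * pi * D * t)) * exp(-z / 4) * (1 - besselI(z, 0, expon.scaled = TRUE))
}

#' Finite-volume solution of the radial diffusion equation
#'
#' Integrates `dP/dt = D * (d2/dr2 + (1/r) d/dr) P` on a disk in
#' conservative finite-volume form: cell-averaged densities, zero-flux
#' inner face at \eqn{r = 0}, absorbing outer boundary (`P(R) = 0`), unit
#' initial mass in the innermost cell (the delta release at the center).
#' Time stepping is backward Euler with a geometrically growing step (see
#' [radial_grid()]); integration stops when the surviving probability mass
#' drops below `1e-6` or `horizon` is reached.
#'
#' @param model [diffusion_model()].
#' @param grid [radial_grid()].
#' @param horizon Optional time horizon (default: run to mass `1e-6`).
#' @return An `fpe_solution` list: `time` and `survival` (the survival
#'   curve), `r` (cell centers), `occupancy` (time-integrated density per
#'   cell, the numerical counterpart of [greens_occupancy()]),
#'   `mean_exit_time` (integral of the survival curve), `grid`, `model`.
#' @export
solve_radial_fpe <- function(model, grid = radial_grid(model$radius),
                             horizon = Inf) {
  stopifnot(inherits(model, "diffusion_model"), inherits(grid, "radial_grid"))
  if (abs(grid$radius - model$radius) > 1e-12 * model$radius)
    stop("grid radius does not match the model radius", call. = FALSE)
  D <- model$D
  R <- model$radius
  n <- grid$n_cells
  rc <- grid$centers
  V <- grid$volumes
  f <- grid$faces
  # interior face conductances: flux = c_i * (u_{i+1} - u_i)
  c_face <- 2 * pi * f[2:n] * D / diff(rc)          # faces 1..n-1
  c_rim <- 2 * pi * R * D / (R - rc[n])             # absorbing boundary
  lower <- c(0, c_face) / V                          # contribution of u_{i-1}
  upper <- c(c_face, 0) / V                          # contribution of u_{i+1}
  diagA <- -(c(0, c_face) + c(c_face, c_rim)) / V

  tau <- R^2 / D
  dt <- grid$dt_init * tau
  dt_max <- grid$dt_max * tau
  u <- numeric(n)
  u[1] <- 1 / V[1]
  occ <- numeric(n)
  t_now <- 0
  times <- 0
  surv <- 1
  mexit <- 0
  repeat {
    dt <- min(dt * grid$growth, dt_max)
    # (I - dt A) u_new = u
    u_new <- cpp_tridiag_solve(-dt * lower, 1 - dt * diagA, -dt * upper, u)
    if (any(!is.finite(u_new)))
      stop("radial solver became unstable; reduce the time step ",
           "(`dt_init`/`dt_max` in radial_grid())", call. = FALSE)
    occ <- occ + dt * (u + u_new) / 2
    s_old <- if (length(surv)) surv[length(surv)] else 1
    s_new <- sum(V * u_new)
    mexit <- mexit + dt * (s_old + s_new) / 2
    t_now <- t_now + dt
    u <- u_new
    times <- c(times, t_now)
    surv <- c(surv, s_new)
    if (s_new < 1e-6 || t_now >= horizon) break
  }
  structure(list(time = times, survival = surv, r = rc, occupancy = occ,
                 mean_exit_time = mexit, grid = grid, model = model),
            class = "fpe_solution")
}

#' @export
print.fpe_solution <- function(x, ...) {
  cat("Radial diffusion solution:", x$grid$n_cells, "cells,",
      length(x$time), "time steps\n")
  cat("  final survival:", format(x$survival[length(x$survival)],
                                  digits = 3),
      " mean exit time:", format(x$mean_exit_time, digits = 5), "\n")
  invisible(x)
}

#' @export
plot.fpe_solution <- function(x, ...) {
  graphics::plot(x$time, x$survival, type = "l", log = "y", xlab = "t",
                 ylab = "surviving probability", ...)
  invisible(x)
}
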