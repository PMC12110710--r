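#' Motility parameters of one movement state
#'
#' A constant-speed active particle whose heading diffuses with angular
#' diffusion coefficient `d_theta` traces a path with persistence length
#' `v0 / d_theta`: the contour distance over which heading correlations
#' decay by 1/e.  One `motility_params` object describes one such state.
#'
#' @param v0 Swimming speed (disk radii per unit time), `>= 0`.
#' @param d_theta Angular diffusion coefficient (radians^2 per unit time),
#'   `>= 0`.  Larger values give tighter, more wiggly paths.
#' @return An object of class `motility_params`.
#' @examples
#' p <- motility_params(v0 = 1, d_theta = 2)
#' persistence_length(p)  # 0.5
#' @export
motility_params <- function(v0, d_theta) {
  stopifnot(is.numeric(v0), length(v0) == 1L, is.finite(v0),
            is.numeric(d_theta), length(d_theta) == 1L, is.finite(d_theta))
  if (v0 < 0) stop("`v0` must be >= 0", call. = FALSE)
  if (d_theta < 0) stop("`d_theta` must be >= 0", call. = FALSE)
  structure(list(v0 = as.numeric(v0), d_theta = as.numeric(d_theta)),
            class = "motility_params")
}

#' Persistence length of a motility state
#'
#' @param params A [motility_params()] object.
#' @return `v0 / d_theta`; `Inf` for a ballistic state (`d_theta = 0` with
#'   `v0 > 0`).
#' @export
persistence_length <- function(params) {
  stopifnot(inherits(params, "motility_params"))
  if (params$d_theta == 0) {
    if (params$v0 > 0) return(Inf)
    return(NaN)  # immobile particle: no path, no persistence length
  }
  params$v0 / params$d_theta
}

#' Kuhn length
#'
#' The equivalent freely jointed chain of a persistent path has segment
#' (Kuhn) length twice the persistence length.
#'
#' @param ell_p Persistence length (or a [motility_params()] object).
#' @return `2 * ell_p`.
#' @export
kuhn_length <- function(ell_p) {
  if (inherits(ell_p, "motility_params")) ell_p <- persistence_length(ell_p)
  stopifnot(is.numeric(ell_p))
  2 * ell_p
}

#' @export
print.motility_params <- function(x, ...) {
  cat("Motility state: v0 =", x$v0, ", D_theta =", x$d_theta, "\n")
  lp <- if (x$d_theta > 0 && x$v0 > 0) x$v0 / x$d_theta else NA
  if (is.finite(lp)) cat("  persistence length v0/D_theta =", lp, "\n")
  invisible(x)
}

#' Switching policy between the two motility states
#'
#' The searcher starts in `state1` and may switch irreversibly to `state2`
#' (a model of hyperactivation: an irreversible drop in persistence length).
#' Three protocols are supported:
#' \describe{
#'   \item{`"constant"`}{no switch; `state1` holds throughout.}
#'   \item{`"rate"`}{the switch happens at an exponentially distributed
#'     waiting time with rate `k` (mean `1/k`).}
#'   \item{`"positional"`}{the switch happens at the end of the first
#'     integration step whose position satisfies \eqn{r \ge r_s}.}
#' }
#'
#' @param mode One of `"constant"`, `"rate"`, `"positional"`.
#' @param state1,state2 [motility_params()] for the initial and final state
#'   (`state2` ignored and may be `NULL` in constant mode).
#' @param k Transition rate per unit time (rate mode only), `> 0`.
#' @param r_switch Trigger radius (positional mode only), `0 < r_switch < R`.
#' @param rate_method How rate-mode switching is realised: `"exponential"`
#'   draws the exact exponential waiting time once at trajectory start
#'   (default); `"bernoulli"` performs per-step Bernoulli(`k * dt`) trials,
#'   which carries an O(dt) bias and exists for comparison.
#' @return An object of class `switch_policy`.
#' @examples
#' baseline <- switch_policy("constant", motility_params(1, 2.0))
#' timed <- switch_policy("rate", motility_params(1, 0.67),
#'                        motility_params(1, 6.0), k = 2.0)
#' @export
switch_policy <- function(mode = c("constant", "rate", "positional"),
                          state1, state2 = NULL, k = NULL, r_switch = NULL,
                          rate_method = c("exponential", "bernoulli")) {
  mode <- match.arg(mode)
  rate_method <- match.arg(rate_method)
  stopifnot(inherits(state1, "motility_params"))
  if (mode != "constant") {
    if (!inherits(state2, "motility_params"))
      stop("`state2` must be supplied for mode '", mode, "'", call. = FALSE)
  }
  if (mode == "rate") {
    if (is.null(k) || !is.numeric(k) || length(k) != 1L || !is.finite(k) ||
        k <= 0)
      stop("rate mode requires a finite transition rate `k` > 0",
           call. = FALSE)
  }
  if (mode == "positional") {
    if (is.null(r_switch) || !is.numeric(r_switch) || length(r_switch) != 1L ||
        !is.finite(r_switch) || r_switch <= 0)
      stop("positional mode requires a trigger radius `r_switch` > 0",
           call. = FALSE)
  }
  structure(list(mode = mode, state1 = state1, state2 = state2,
                 k = if (mode == "rate") as.numeric(k) else NULL,
                 r_switch = if (mode == "positional") as.numeric(r_switch)
                            else NULL,
                 rate_method = rate_method),
            class = "switch_policy")
}

#' @export
print.switch_policy <- function(x, ...) {
  cat("Switch policy:", x$mode, "\n")
  cat("  state 1: v0 =", x$state1$v0, ", D_theta =", x$state1$d_theta, "\n")
  if (x$mode != "constant")
    cat("  state 2: v0 =", x$state2$v0, ", D_theta =", x$state2$d_theta, "\n")
  if (x$mode == "rate")
    cat("  transition rate k =", x$k, "(", x$rate_method, ")\n")
  if (x$mode == "positional")
    cat("  trigger radius r_switch =", x$r_switch, "\n")
  invisible(x)
}

#' Disk search domain
#'
#' @param radius Disk radius; the rim \eqn{r = radius} is absorbing.  All
#'   reference experiments use the unit disk.
#' @return An object of class `disk_domain`.
#' @export
disk_domain <- function(radius = 1) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius),
            radius > 0)
  structure(list(radius = as.numeric(radius)), class = "disk_domain")
}

#' Simulation configuration
#'
#' @param dt Integration timestep (default 0.001, the reference value for
#'   the unit-disk experiments).
#' @param t_max Censoring horizon: a trajectory still inside the disk at
#'   `t_max` is returned censored (default 1000, far above all mean escape
#'   times of the reference protocols).
#' @param n_trajectories Ensemble size.
#' @param seed Root RNG seed; trajectory `i` runs on an independent
#'   substream derived from `(seed, i)`.
#' @param record_stride Store every `record_stride`-th integration step when
#'   a full path is requested.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1e-3, t_max = 1000, n_trajectories = 1L,
                       seed = 1L, record_stride = 1L) {
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0,
            is.numeric(t_max), length(t_max) == 1L, is.finite(t_max),
            t_max > 0,
            is.numeric(n_trajectories), length(n_trajectories) == 1L,
            n_trajectories >= 1,
            is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(record_stride), length(record_stride) == 1L,
            record_stride >= 1)
  structure(list(dt = as.numeric(dt), t_max = as.numeric(t_max),
                 n_trajectories = as.integer(n_trajectories),
                 seed = as.numeric(seed),
                 record_stride = as.integer(record_stride)),
            class = "sim_config")
}

#' Radial binning of the disk
#'
#' The disk is divided into a small central circle of radius `radius/n_bins`
#' plus `n_bins - 1` annuli of equal width, the segmentation used by all
#' coverage statistics (default: 20 regions of width 0.05 on the unit disk).
#'
#' @param radius Disk radius.
#' @param n_bins Number of radial regions.
#' @return An object of class `radial_binning` with elements `edges`
#'   (length `n_bins + 1`), `area`, and `midpoint` per region.
#' @export
radial_binning <- function(radius = 1, n_bins = 20L) {
  stopifnot(is.numeric(radius), radius > 0, is.numeric(n_bins), n_bins >= 1)
  n_bins <- as.integer(n_bins)
  edges <- seq(0, radius, length.out = n_bins + 1L)
  area <- diff(pi * edges^2)
  structure(list(radius = as.numeric(radius), n_bins = n_bins, edges = edges,
                 area = area, midpoint = (edges[-1] + edges[-(n_bins + 1L)]) / 2),
            class = "radial_binning")
}

#' Coarse-grained diffusion model
#'
#' Container for the translational diffusion coefficient that describes the
#' active walk on scales far beyond its persistence length, together with
#' the disk radius; all closed-form theory functions take one of these.
#'
#' @param D Translational diffusion coefficient (area per unit time), `> 0`.
#' @param radius Disk radius, `> 0`.
#' @return An object of class `diffusion_model`.
#' @seealso [effective_diffusion()] to obtain `D` from motility parameters.
#' @export
diffusion_model <- function(D, radius = 1) {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D), D > 0,
            is.numeric(radius), length(radius) == 1L, is.finite(radius),
            radius > 0)
  structure(list(D = as.numeric(D), radius = as.numeric(radius)),
            class = "diffusion_model")
}

#' @export
print.diffusion_model <- function(x, ...) {
  cat("Radial diffusion model: D =", x$D, ", R =", x$radius, "\n")
  cat("  mean exit time from the center R^2/(4D) =", x$radius^2 / (4 * x$D),
      "\n")
  invisible(x)
}

#' Radial finite-volume grid for the diffusion solver
#'
#' Cells of equal width on `[0, R]`; the inner face at \eqn{r = 0} is a
#' zero-flux (reflecting) face and the outer boundary is absorbing.  The
#' time stepping is implicit (backward Euler) with a geometrically growing
#' step: the delta initial condition needs tiny early steps, while the
#' slow late-time relaxation tolerates much larger ones.  Step controls are
#' expressed as fractions of the diffusion time `R^2/D` and resolved when
#' the solver runs.
#'
#' @param radius Disk radius.
#' @param n_cells Number of cells (default 400, set by grid-refinement
#'   convergence checks in the test suite).
#' @param dt_init Initial time step as a fraction of `R^2/D`.
#' @param dt_max Maximum time step as a fraction of `R^2/D`.
#' @param growth Per-step geometric growth factor of the time step.
#' @return An object of class `radial_grid`.
#' @export
radial_grid <- function(radius = 1, n_cells = 400L, dt_init = 1e-7,
                        dt_max = 2.5e-4, growth = 1.02) {
  stopifnot(is.numeric(radius), radius > 0, is.numeric(n_cells), n_cells >= 10,
            dt_init > 0, dt_max >= dt_init, growth >= 1)
  n_cells <- as.integer(n_cells)
  faces <- seq(0, radius, length.out = n_cells + 1L)
  structure(list(radius = as.numeric(radius), n_cells = n_cells,
                 faces = faces,
                 centers = (faces[-1] + faces[-(n_cells + 1L)]) / 2,
                 volumes = diff(pi * faces^2),
                 dt_init = dt_init, dt_max = dt_max, growth = growth),
            class = "radial_grid")
}
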