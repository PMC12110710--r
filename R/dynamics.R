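#' One Euler-Maruyama step of the active-particle dynamics
#'
#' Advances position and heading by one timestep: the displacement uses the
#' pre-step heading and has length exactly `v0 * dt` (constant speed), then
#' the heading receives the increment `sqrt(2 * d_theta * dt) * noise`.
#' Vectorised over `x`, `y`, `theta`, `noise`.  This is the reference
#' (pure-R) form of the update; the simulators apply the identical rule in
#' compiled code.
#'
#' @param x,y Position.
#' @param theta Heading (radians).
#' @param params [motility_params()].
#' @param dt Timestep, `> 0`.
#' @param noise Standard-normal deviate(s) driving the heading update.
#' @return A list with components `x`, `y`, `theta` after the step.
#' @examples
#' advance_step(0, 0, 0, motility_params(1, 0), dt = 1e-3, noise = 0.7)
#' @export
advance_step <- function(x, y, theta, params, dt, noise) {
  stopifnot(inherits(params, "motility_params"),
            is.numeric(dt), length(dt) == 1L)
  if (!all(is.finite(x), is.finite(y), is.finite(theta), is.finite(dt),
           is.finite(noise)))
    stop("advance_step: all inputs must be finite", call. = FALSE)
  if (dt <= 0) stop("advance_step: `dt` must be > 0", call. = FALSE)
  list(x = x + params$v0 * dt * cos(theta),
       y = y + params$v0 * dt * sin(theta),
       theta = theta + sqrt(2 * params$d_theta * dt) * noise)
}

#' Draw exponential switching times
#'
#' Waiting times of the rate-mode state transition: exponentially
#' distributed with rate `k` (mean `1/k`).  Uses R's RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' @param k Transition rate, `> 0`.
#' @param n Number of draws.
#' @return Numeric vector of waiting times.
#' @export
draw_switch_time <- function(k, n = 1L) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("`k` must be a finite rate > 0", call. = FALSE)
  stats::rexp(n, rate = k)
}

mode_code <- function(policy) {
  c(constant = 0L, rate = 1L, positional = 2L)[[policy$mode]]
}

policy_cpp_args <- function(policy, domain) {
  s2 <- if (policy$mode == "constant") policy$state1 else policy$state2
  if (policy$mode == "positional" && policy$r_switch >= domain$radius)
    stop("`r_switch` must be smaller than the disk radius", call. = FALSE)
  list(mode = mode_code(policy),
       v1 = policy$state1$v0, d1 = policy$state1$d_theta,
       v2 = s2$v0, d2 = s2$d_theta,
       k = if (is.null(policy$k)) 0 else policy$k,
       r_switch = if (is.null(policy$r_switch)) 0 else policy$r_switch,
       bernoulli = identical(policy$rate_method, "bernoulli"))
}

#' Simulate one trajectory on the disk
#'
#' Integrates the motility dynamics from the disk center (uniform random
#' initial heading) until the first step end-point with \eqn{r \ge R}
#' (absorption) or until `t_max` (censoring, returned with a warning, never
#' an error).  Trajectory `traj_index` of an ensemble run with the same
#' config is reproduced exactly.
#'
#' @param config [sim_config()].
#' @param policy [switch_policy()].
#' @param domain [disk_domain()].
#' @param traj_index Which RNG substream to use (1-based); trajectory `i`
#'   here is identical to member `i` of [simulate_ensemble()] under the
#'   same seed.
#' @return A `search_trajectory`: a data frame with columns `t`, `x`, `y`,
#'   `theta`, `state` (recorded every `record_stride` steps, plus the
#'   terminal point) and attributes `escape_time`, `absorbed`,
#'   `switch_time`, `switch_radius`, `contour_step`, `params`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' pol <- switch_policy("constant", motility_params(1, 2))
#' tr <- simulate_trajectory(cfg, pol, disk_domain())
#' attr(tr, "escape_time")
#' @export
simulate_trajectory <- function(config, policy, domain = disk_domain(),
                                traj_index = 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(policy, "switch_policy"),
            inherits(domain, "disk_domain"), traj_index >= 1)
  a <- policy_cpp_args(policy, domain)
  res <- cpp_run_path(config$seed, as.integer(traj_index), a$mode, a$v1, a$d1,
                      a$v2, a$d2, a$k, a$r_switch, a$bernoulli, domain$radius,
                      config$dt, config$t_max, config$record_stride)
  if (!res$absorbed)
    warning("trajectory censored at t_max = ", config$t_max,
            " without reaching the rim", call. = FALSE)
  out <- data.frame(t = res$t, x = res$x, y = res$y, theta = res$theta,
                    state = res$state)
  structure(out,
            class = c("search_trajectory", "data.frame"),
            escape_time = res$escape_time, absorbed = res$absorbed,
            switched = res$switched,
            switch_time = if (res$switched) res$switch_time else NA_real_,
            switch_radius = if (res$switched) res$switch_radius else NA_real_,
            contour_step = policy$state1$v0 * config$dt * config$record_stride,
            domain = domain, config = config, policy = policy)
}

#' Simulate an ensemble of independent searchers
#'
#' Runs `n_trajectories` independent trajectories, each on its own RNG
#' substream derived from `(seed, index)`, so results are identical
#' regardless of execution order or batching.  Full paths are not stored;
#' instead each trajectory streams its per-region dwell times (each
#' integration step credits its full `dt` to the region containing the
#' step's start point) together with escape-time and switching summaries.
#'
#' @inheritParams simulate_trajectory
#' @param binning [radial_binning()] used to accumulate dwell times
#'   (default: the 20-region segmentation of the domain).
#' @return A `search_ensemble`: list with `escape_time`, `absorbed`,
#'   `switched`, `switch_time`, `switch_radius`, `exit_azimuth` (one entry
#'   per trajectory), the per-trajectory `dwell` matrix
#'   (`n_trajectories x n_bins`), `n_censored`, and the inputs.
#' @examples
#' cfg <- sim_config(n_trajectories = 50, seed = 1)
#' pol <- switch_policy("constant", motility_params(1, 2))
#' ens <- simulate_ensemble(cfg, pol)
#' mean_escape_time(ens)
#' @export
simulate_ensemble <- function(config, policy, domain = disk_domain(),
                              binning = radial_binning(domain$radius, 20L)) {
  stopifnot(inherits(config, "sim_config"), inherits(policy, "switch_policy"),
            inherits(domain, "disk_domain"),
            inherits(binning, "radial_binning"))
  if (abs(binning$radius - domain$radius) > 1e-12 * domain$radius)
    stop("binning radius does not match the domain radius", call. = FALSE)
  a <- policy_cpp_args(policy, domain)
  res <- cpp_run_ensemble(config$n_trajectories, config$seed, a$mode, a$v1,
                          a$d1, a$v2, a$d2, a$k, a$r_switch, a$bernoulli,
                          domain$radius, config$dt, config$t_max,
                          binning$n_bins)
  n_cens <- sum(!res$absorbed)
  if (n_cens / config$n_trajectories > 0.001)
    warning(n_cens, " of ", config$n_trajectories,
            " trajectories censored at t_max = ", config$t_max, call. = FALSE)
  structure(list(escape_time = res$escape_time, absorbed = res$absorbed,
                 switched = res$switched, switch_time = res$switch_time,
                 switch_radius = res$switch_radius,
                 exit_azimuth = res$exit_azimuth, dwell = res$dwell,
                 n_censored = n_cens, binning = binning, config = config,
                 policy = policy, domain = domain),
            class = "search_ensemble")
}

#' @export
print.search_ensemble <- function(x, ...) {
  n <- x$config$n_trajectories
  cat("Search ensemble:", n, "trajectories,", x$policy$mode, "protocol\n")
  cat("  absorbed:", sum(x$absorbed), " censored:", x$n_censored, "\n")
  if (any(x$absorbed))
    cat("  mean escape time:",
        format(mean(x$escape_time[x$absorbed]), digits = 4), "\n")
  invisible(x)
}

#' @export
summary.search_ensemble <- function(object, ...) {
  coverage_uniformity(bin_occupancy(object))
}

#' @export
print.search_trajectory <- function(x, ...) {
  cat("Search trajectory:", nrow(x), "recorded points\n")
  cat("  absorbed:", attr(x, "absorbed"),
      " escape/censor time:", format(attr(x, "escape_time"), digits = 4), "\n")
  if (isTRUE(attr(x, "switched")))
    cat("  state switch at t =", format(attr(x, "switch_time"), digits = 4),
        ", r =", format(attr(x, "switch_radius"), digits = 4), "\n")
  invisible(x)
}

#' @export
plot.search_trajectory <- function(x, ...) {
  R <- attr(x, "domain")$radius
  phi <- seq(0, 2 * pi, length.out = 361)
  graphics::plot(R * cos(phi), R * sin(phi), type = "l", lty = 2, asp = 1,
                 xlab = "x", ylab = "y", ...)
  cols <- c("firebrick", "steelblue")[x$state]
  graphics::segments(x$x[-nrow(x)], x$y[-nrow(x)], x$x[-1], x$y[-1],
                     col = cols[-nrow(x)])
  invisible(x)
}
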