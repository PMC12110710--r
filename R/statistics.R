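#' Per-region dwell-time densities of a search
#'
#' Splits the disk into the regions of `binning` and computes, per region,
#' the ensemble-mean dwell time `dT` and the dwell-time density `dT/dA`.
#' Each integration step credits its full `dt` to the region containing the
#' step's start point, so the dwell times of one trajectory sum exactly to
#' its escape (or censoring) time.
#'
#' @param x A `search_ensemble`, a `search_trajectory`, or a list of
#'   `search_trajectory` objects.
#' @param binning [radial_binning()]; for ensembles it must equal the
#'   binning used during simulation (dwell times are accumulated on the
#'   fly) and defaults to it.
#' @param ... Unused.
#' @return An `occupancy_profile`: data frame with columns `region`,
#'   `r_inner`, `r_outer`, `area`, `dwell_time`, `density`, plus attributes
#'   `binning`, `n_trajectories`, `n_absorbed`, `n_censored`, `mean_time`
#'   (mean escape/censoring time) and `mean_escape_time` (absorbed only).
#' @examples
#' ens <- simulate_ensemble(sim_config(n_trajectories = 100, seed = 1),
#'                          switch_policy("constant", motility_params(1, 2)))
#' prof <- bin_occupancy(ens)
#' sum(prof$dwell_time) - mean(ens$escape_time)  # 0: dwell conservation
#' @export
bin_occupancy <- function(x, binning = NULL, ...) UseMethod("bin_occupancy")

#' @export
bin_occupancy.search_ensemble <- function(x, binning = NULL, ...) {
  if (is.null(binning)) binning <- x$binning
  if (!isTRUE(all.equal(binning$edges, x$binning$edges)))
    stop("ensemble dwell times were accumulated on a different binning; ",
         "re-run simulate_ensemble() with the desired binning",
         call. = FALSE)
  dwell <- colMeans(x$dwell)
  new_occupancy_profile(dwell, binning,
                        n_trajectories = x$config$n_trajectories,
                        n_absorbed = sum(x$absorbed),
                        n_censored = x$n_censored,
                        mean_time = mean(x$escape_time),
                        mean_escape_time = if (any(x$absorbed))
                          mean(x$escape_time[x$absorbed]) else NA_real_)
}

#' @export
bin_occupancy.search_trajectory <- function(x, binning = NULL, ...) {
  bin_occupancy(list(x), binning = binning)
}

#' @export
bin_occupancy.list <- function(x, binning = NULL, ...) {
  if (length(x) == 0L) stop("empty ensemble", call. = FALSE)
  if (is.null(binning)) {
    dom <- attr(x[[1]], "domain")
    binning <- radial_binning(dom$radius, 20L)
  }
  stopifnot(inherits(binning, "radial_binning"))
  R <- binning$radius
  dwell <- matrix(0, length(x), binning$n_bins)
  times <- numeric(length(x))
  absorbed <- logical(length(x))
  for (i in seq_along(x)) {
    tr <- x[[i]]
    stopifnot(inherits(tr, "search_trajectory"))
    r <- sqrt(tr$x^2 + tr$y^2)
    if (any(r[-length(r)] >= R))
      stop("non-terminal position at r >= R: trajectory inconsistent with ",
           "the binning domain", call. = FALSE)
    # start point of each recorded step; steps are uniform in time
    dts <- diff(tr$t)
    idx <- pmin(findInterval(r[-length(r)], binning$edges,
                             rightmost.closed = FALSE) , binning$n_bins)
    dwell[i, ] <- as.numeric(tapply(dts, factor(idx, levels = seq_len(binning$n_bins)),
                                    sum, default = 0))
    times[i] <- tr$t[length(tr$t)]
    absorbed[i] <- isTRUE(attr(tr, "absorbed"))
  }
  new_occupancy_profile(colMeans(dwell), binning,
                        n_trajectories = length(x),
                        n_absorbed = sum(absorbed),
                        n_censored = sum(!absorbed),
                        mean_time = mean(times),
                        mean_escape_time = if (any(absorbed))
                          mean(times[absorbed]) else NA_real_)
}

new_occupancy_profile <- function(dwell, binning, n_trajectories, n_absorbed,
                                  n_censored, mean_time, mean_escape_time) {
  out <- data.frame(region = seq_len(binning$n_bins),
                    r_inner = binning$edges[-(binning$n_bins + 1L)],
                    r_outer = binning$edges[-1],
                    area = binning$area,
                    dwell_time = dwell,
                    density = dwell / binning$area)
  structure(out, class = c("occupancy_profile", "data.frame"),
            binning = binning, n_trajectories = n_trajectories,
            n_absorbed = n_absorbed, n_censored = n_censored,
            mean_time = mean_time, mean_escape_time = mean_escape_time)
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat("Occupancy profile over", nrow(x), "radial regions",
      "(", attr(x, "n_trajectories"), "trajectories )\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.occupancy_profile <- function(x, theory = NULL, ...) {
  mid <- attr(x, "binning")$midpoint
  graphics::barplot(x$density, width = diff(attr(x, "binning")$edges),
                    space = 0, xlab = "r", ylab = expression(Delta*T/Delta*A),
                    ...)
  graphics::axis(1, at = pretty(c(0, attr(x, "binning")$radius)))
  if (!is.null(theory))
    graphics::lines(mid, theory(mid), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Coverage uniformity of an occupancy profile
#'
#' The search-quality metric: mean and standard deviation of the per-region
#' dwell-time densities, and their ratio (the relative standard deviation).
#' A perfectly uniform search has relative standard deviation 0.
#'
#' @param profile An `occupancy_profile`.
#' @return A `search_summary` list with `mean_escape_time`, `density_mean`,
#'   `density_std`, `relative_std`, `n_absorbed`, `n_censored`,
#'   `n_trajectories`.
#' @export
coverage_uniformity <- function(profile) {
  stopifnot(inherits(profile, "occupancy_profile"))
  m <- mean(profile$density)
  s <- stats::sd(profile$density)
  if (m == 0) stop("mean density is zero: relative std undefined",
                   call. = FALSE)
  structure(list(mean_escape_time = attr(profile, "mean_escape_time"),
                 density_mean = m, density_std = s, relative_std = s / m,
                 n_absorbed = attr(profile, "n_absorbed"),
                 n_censored = attr(profile, "n_censored"),
                 n_trajectories = attr(profile, "n_trajectories")),
            class = "search_summary")
}

#' @export
print.search_summary <- function(x, ...) {
  cat("Search summary (", x$n_trajectories, "trajectories,", x$n_absorbed,
      "absorbed,", x$n_censored, "censored )\n")
  cat("  mean escape time   :", format(x$mean_escape_time, digits = 4), "\n")
  cat("  density mean / std :", format(x$density_mean, digits = 4), "/",
      format(x$density_std, digits = 4), "\n")
  cat("  relative std       :", format(x$relative_std, digits = 4), "\n")
  invisible(x)
}

#' Mean first-passage (escape) time
#'
#' Arithmetic mean of the escape times of the absorbed trajectories;
#' censored trajectories are excluded (and counted in the ensemble object).
#'
#' @param x A `search_ensemble` or `search_trajectory`.
#' @return Mean escape time.
#' @export
mean_escape_time <- function(x) UseMethod("mean_escape_time")

#' @export
mean_escape_time.search_ensemble <- function(x) {
  if (!any(x$absorbed))
    stop("all trajectories censored: escape time not estimable",
         call. = FALSE)
  mean(x$escape_time[x$absorbed])
}

#' @export
mean_escape_time.search_trajectory <- function(x) {
  if (!isTRUE(attr(x, "absorbed")))
    stop("trajectory censored: no escape time", call. = FALSE)
  attr(x, "escape_time")
}

#' Tangent-angle correlation along a trajectory
#'
#' Estimates `<cos(delta theta(l))>`, the mean cosine of the heading change
#' over contour distance `l`, whose exponential decay defines the
#' persistence length.  By default the average runs over non-overlapping
#' segments of length `l` along the contour; `overlapping = TRUE` uses
#' every start point (lower variance, correlated samples).
#'
#' @param traj A `search_trajectory` (or any object with a `theta` column
#'   and a `contour_step` attribute giving the contour spacing between
#'   consecutive recorded headings).
#' @param lags Contour-length lags; rounded to multiples of the contour
#'   step.  Default: 40 lags spanning up to a quarter of the contour.
#' @param overlapping Use overlapping windows instead of the default
#'   non-overlapping segments.
#' @return A `persistence_fit` data frame with columns `ell`,
#'   `correlation`, `n_pairs`; feed to [estimate_persistence_length()].
#' @export
tangent_correlation <- function(traj, lags = NULL, overlapping = FALSE) {
  theta <- traj$theta
  ds <- attr(traj, "contour_step")
  if (is.null(ds) || !is.finite(ds) || ds <= 0)
    stop("trajectory lacks a positive `contour_step` attribute",
         call. = FALSE)
  n <- length(theta)
  contour <- (n - 1) * ds
  if (is.null(lags)) {
    # log-spaced lags so that the decaying region is well resolved
    # whatever the (unknown) persistence length
    m_max <- max(1L, floor((n - 1) / 4))
    offs <- unique(pmax(1L, round(exp(seq(0, log(m_max),
                                          length.out = 60L)))))
    lags <- offs * ds
  } else {
    offs <- as.integer(round(lags / ds))
    lags <- offs * ds
  }
  if (any(lags > contour / 2))
    stop("lag exceeds half the contour length (", format(contour / 2),
         "): insufficient data", call. = FALSE)
  keep0 <- offs == 0L
  corr <- numeric(length(offs))
  npair <- integer(length(offs))
  for (j in seq_along(offs)) {
    m <- offs[j]
    if (m == 0L) {
      corr[j] <- 1
      npair[j] <- n
      next
    }
    if (overlapping) {
      d <- theta[(m + 1L):n] - theta[1L:(n - m)]
    } else {
      idx <- seq(1L, n, by = m)
      d <- diff(theta[idx])
    }
    corr[j] <- mean(cos(d))
    npair[j] <- length(d)
  }
  structure(data.frame(ell = lags, correlation = corr, n_pairs = npair),
            class = c("persistence_fit", "data.frame"),
            contour_length = contour, overlapping = overlapping)
}

#' Persistence length from a tangent-correlation curve
#'
#' Fits `log(correlation) = -ell / ell_p` by least squares (through the
#' origin, since the correlation is exactly 1 at zero lag) over the lags in
#' `fit_range`; by default all positive lags before the correlation first
#' drops to 0.1, where the exponential law is well resolved above sampling
#' noise.
#'
#' @param fit A `persistence_fit` from [tangent_correlation()].
#' @param fit_range Optional length-2 numeric giving the lag interval to
#'   use instead of the default rule.
#' @return The fitted persistence length (attribute `fit_range` records the
#'   lags used).  For a path with no measurable decay (e.g. perfectly
#'   straight) the estimate is `Inf` with attribute `lower_bound` set to
#'   the largest lag probed: the data only bound the persistence length
#'   from below.
#' @export
estimate_persistence_length <- function(fit, fit_range = NULL) {
  stopifnot(inherits(fit, "persistence_fit"))
  ord <- order(fit$ell)
  fit <- fit[ord, , drop = FALSE]
  use <- fit$ell > 0
  if (is.null(fit_range)) {
    # lags before the correlation first drops to 0.1: beyond that point
    # the estimates are sampling noise around zero and would wreck the
    # log-linear fit
    below <- which(use & fit$correlation <= 0.1)
    if (length(below)) use <- use & seq_len(nrow(fit)) < min(below)
    use <- use & fit$correlation > 0
  } else {
    stopifnot(length(fit_range) == 2L)
    use <- use & fit$ell >= fit_range[1] & fit$ell <= fit_range[2] &
      fit$correlation > 0
  }
  if (sum(use) < 3L)
    stop("fewer than 3 usable lags with positive correlation: cannot ",
         "estimate the persistence length", call. = FALSE)
  ell <- fit$ell[use]
  lc <- log(fit$correlation[use])
  slope <- sum(ell * lc) / sum(ell^2)
  if (slope >= 0) {
    # no decay measurable over the probed lags
    out <- Inf
    attr(out, "lower_bound") <- max(ell)
    attr(out, "fit_range") <- range(ell)
    return(out)
  }
  out <- -1 / slope
  attr(out, "fit_range") <- range(ell)
  out
}

#' @export
plot.persistence_fit <- function(x, ...) {
  graphics::plot(x$ell, x$correlation, xlab = "contour lag l",
                 ylab = expression(group("<", cos * Delta * theta(l), ">")),
                 ...)
  lp <- tryCatch(estimate_persistence_length(x), error = function(e) NULL)
  if (!is.null(lp) && is.finite(lp))
    graphics::curve(exp(-x / lp), add = TRUE, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Freely-jointed-chain relations
#'
#' For a chain of `N` rigid segments of Kuhn length `ell_k`: total contour
#' length `L = N * ell_k` and mean-square end-to-end distance
#' `<S^2> = N * ell_k^2`.
#'
#' @param N Number of Kuhn segments, `>= 1`.
#' @param ell_k Kuhn length, `> 0`.
#' @return List with `L` and `S2`.
#' @examples
#' fjc_relations(1000, 0.01)  # L = 10, S2 = 0.1
#' @export
fjc_relations <- function(N, ell_k) {
  stopifnot(is.numeric(N), N >= 1, is.numeric(ell_k), ell_k > 0)
  list(L = N * ell_k, S2 = N * ell_k^2)
}

#' Sample freely jointed chains
#'
#' Draws `n_chains` independent FJC realisations (segment orientations
#' uniform on `[0, 2*pi)`) and returns the squared end-to-end distance of
#' each; a Monte-Carlo check of [fjc_relations()].  Uses R's RNG.
#'
#' @param n_chains Number of chains.
#' @param N Segments per chain.
#' @param ell_k Kuhn length.
#' @return Numeric vector of squared end-to-end distances.
#' @export
simulate_fjc <- function(n_chains, N, ell_k) {
  stopifnot(n_chains >= 1, N >= 1, ell_k > 0)
  ang <- matrix(stats::runif(n_chains * N, 0, 2 * pi), nrow = N)
  (ell_k * colSums(cos(ang)))^2 + (ell_k * colSums(sin(ang)))^2
}

#' Slope of the dwell-time density near the rim
#'
#' Ordinary least-squares line through the points (region midpoint radius,
#' density) of the `n_outer` outermost regions; returns the magnitude of
#' the slope.  Near an absorbing rim the density falls off linearly, with
#' theoretical slope magnitude `1/(2*pi*D*R)` in the diffusive limit
#' (see [rim_slope()]).
#'
#' @param profile An `occupancy_profile`.
#' @param n_outer Number of outermost regions to fit (default 4).
#' @return `|slope|`, with attributes `slope` (signed), `intercept`, and
#'   `r` (the abscissae used).
#' @export
fit_outer_slope <- function(profile, n_outer = 4L) {
  stopifnot(inherits(profile, "occupancy_profile"))
  if (n_outer < 2L) stop("`n_outer` must be at least 2", call. = FALSE)
  n <- nrow(profile)
  if (n < n_outer) stop("profile has fewer than `n_outer` regions",
                        call. = FALSE)
  sel <- (n - n_outer + 1L):n
  r <- attr(profile, "binning")$midpoint[sel]
  d <- profile$density[sel]
  co <- stats::coef(stats::lm(d ~ r))
  out <- abs(co[["r"]])
  attr(out, "slope") <- co[["r"]]
  attr(out, "intercept") <- co[["(Intercept)"]]
  attr(out, "r") <- r
  out
}
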