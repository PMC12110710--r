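#' Write a trajectory table
#'
#' Plain-text tab-delimited table with header and columns `traj_id`, `t`,
#' `x`, `y`, `theta`, `state`.
#'
#' @param traj A `search_trajectory` or a list of them.
#' @param file Output path.
#' @param traj_id Id (or ids) to write in the `traj_id` column.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file, traj_id = NULL) {
  if (inherits(traj, "search_trajectory")) traj <- list(traj)
  if (is.null(traj_id)) traj_id <- seq_along(traj)
  stopifnot(length(traj_id) == length(traj))
  tabs <- lapply(seq_along(traj), function(i) {
    tr <- traj[[i]]
    data.frame(traj_id = traj_id[i], t = tr$t, x = tr$x, y = tr$y,
               theta = tr$theta, state = tr$state)
  })
  utils::write.table(do.call(rbind, tabs), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read recorded 2D tracks
#'
#' Reads a delimited table of externally recorded tracks with required
#' columns `track_id`, `t`, `x`, `y` (extra columns are kept).  The
#' delimiter is sniffed from the header line (tab or comma).
#'
#' @param file Path to the track table.
#' @return A data frame.
#' @export
read_tracks <- function(file) {
  if (!file.exists(file)) stop("track file not found: ", file, call. = FALSE)
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- tryCatch(utils::read.table(file, header = TRUE, sep = sep,
                                   stringsAsFactors = FALSE),
                 error = function(e)
                   stop("cannot parse track file ", file, ": ",
                        conditionMessage(e), call. = FALSE))
  need <- c("track_id", "t", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("track file ", file, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("t", "x", "y")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop("track file ", file, ": non-numeric value in column '", col,
           "', row ", bad[1], call. = FALSE)
  }
  df
}

#' Resample a track to uniform contour spacing
#'
#' Converts one recorded track into headings at uniform arc-length spacing
#' (linear interpolation of the path), the form required by
#' [tangent_correlation()].
#'
#' @param track Data frame with columns `t`, `x`, `y` (one track).
#' @param ds Contour spacing; default: median step length of the track.
#' @return An object usable by [tangent_correlation()]: data frame with a
#'   `theta` column and a `contour_step` attribute.
#' @export
resample_track <- function(track, ds = NULL) {
  stopifnot(all(c("x", "y") %in% names(track)), nrow(track) >= 3)
  step <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  s <- c(0, cumsum(step))
  if (is.null(ds)) ds <- stats::median(step[step > 0])
  if (!is.finite(ds) || ds <= 0)
    stop("track has no positive displacement: cannot resample",
         call. = FALSE)
  grid <- seq(0, s[length(s)], by = ds)
  xs <- stats::approx(s, track$x, xout = grid, ties = "ordered")$y
  ys <- stats::approx(s, track$y, xout = grid, ties = "ordered")$y
  theta <- atan2(diff(ys), diff(xs))
  # unwrap so that heading differences are continuous
  theta <- theta[1] + c(0, cumsum(((diff(theta) + pi) %% (2 * pi)) - pi))
  structure(data.frame(theta = theta), contour_step = ds,
            class = c("resampled_track", "data.frame"))
}

#' Write an occupancy table
#'
#' Tab-delimited table with columns `region_index`, `r_inner`, `r_outer`,
#' `area`, `dwell_time`, `density`.
#'
#' @param profile An `occupancy_profile`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_occupancy <- function(profile, file) {
  stopifnot(inherits(profile, "occupancy_profile"))
  out <- data.frame(region_index = profile$region, r_inner = profile$r_inner,
                    r_outer = profile$r_outer, area = profile$area,
                    dwell_time = profile$dwell_time,
                    density = profile$density)
  utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a search summary as JSON
#'
#' @param summary A `search_summary` from [coverage_uniformity()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_summary <- function(summary, file) {
  stopifnot(inherits(summary, "search_summary"))
  jsonlite::write_json(unclass(summary), file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}

resolved_config <- function(config, policy, domain) {
  out <- list(dt = config$dt, t_max = config$t_max,
              n_trajectories = config$n_trajectories, seed = config$seed,
              record_stride = config$record_stride,
              radius = domain$radius, protocol = policy$mode,
              v0 = policy$state1$v0, dtheta1 = policy$state1$d_theta)
  if (policy$mode != "constant") {
    out$v0_2 <- policy$state2$v0
    out$dtheta2 <- policy$state2$d_theta
  }
  if (policy$mode == "rate") {
    out$k <- policy$k
    out$rate_method <- policy$rate_method
  }
  if (policy$mode == "positional") out$r_switch <- policy$r_switch
  out
}

#' Write the fully resolved configuration of a run
#'
#' Every run writes its resolved configuration (including the seed) next to
#' its outputs so the run can be reproduced bit-exactly.
#'
#' @param config,policy,domain The run inputs.
#' @param file Output path (`.yaml` or `.json`).
#' @return `file`, invisibly.
#' @export
write_config <- function(config, policy, domain, file) {
  cfg <- resolved_config(config, policy, domain)
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(cfg, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, file)
  }
  invisible(file)
}

#' Read a configuration file
#'
#' Flat key-value YAML or JSON document mirroring the simulation
#' configuration, switch policy and domain; the inverse of
#' [write_config()].
#'
#' @param file Path (`.yaml`/`.yml` or `.json`).
#' @return A list with elements `config` ([sim_config()]), `policy`
#'   ([switch_policy()]), `domain` ([disk_domain()]).
#' @export
read_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", file)) jsonlite::read_json(file,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(file)
  config_from_list(raw)
}

config_from_list <- function(raw) {
  grab <- function(key, default = NULL) {
    if (!is.null(raw[[key]])) raw[[key]] else default
  }
  protocol <- grab("protocol", "constant")
  if (!protocol %in% c("constant", "rate", "positional"))
    stop("invalid config key `protocol`: ", protocol, call. = FALSE)
  v0 <- grab("v0", 1)
  s1 <- motility_params(v0, grab("dtheta1", grab("dtheta", 2)))
  s2 <- if (protocol == "constant") NULL else
    motility_params(grab("v0_2", v0), grab("dtheta2"))
  policy <- switch_policy(protocol, s1, s2, k = grab("k"),
                          r_switch = grab("r_switch"),
                          rate_method = grab("rate_method", "exponential"))
  config <- sim_config(dt = grab("dt", 1e-3), t_max = grab("t_max", 1000),
                       n_trajectories = grab("n_trajectories", 1L),
                       seed = grab("seed", 1L),
                       record_stride = grab("record_stride", 1L))
  list(config = config, policy = policy,
       domain = disk_domain(grab("radius", 1)))
}

#' Write a run manifest
#'
#' JSON record sufficient to reproduce a run bit-exactly: the resolved
#' configuration, seed, package version, trajectory counters, and the
#' output paths.  Written atomically (temp file + rename).
#'
#' @param config,policy,domain The run inputs.
#' @param counters Named list, e.g. `list(n_absorbed = ..., n_censored = ...)`.
#' @param outputs Character vector of output file paths.
#' @param file Manifest path.
#' @return `file`, invisibly.
#' @export
write_manifest <- function(config, policy, domain, counters, outputs, file) {
  man <- list(package = "disksearch",
              version = as.character(utils::packageVersion("disksearch")),
              config = resolved_config(config, policy, domain),
              counters = counters,
              outputs = as.list(outputs))
  tmp <- paste0(file, ".tmp")
  jsonlite::write_json(man, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, file)
  invisible(file)
}
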