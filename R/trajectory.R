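#' Open-field arena
#'
#' Defines the arena the virtual animal explores. Positions live in
#' \code{[0, extent] x [0, extent]} metres; a circular arena is the inscribed
#' circle of that square (the default 2 m arena is centred at (1, 1)).
#'
#' @param shape \code{"circle"} or \code{"square"}.
#' @param extent Diameter (circle) or side length (square) in metres.
#' @return An object of class \code{can_arena}.
#' @examples
#' a <- can_arena("circle", 2)
#' arena_contains(a, 1, 1)
#' @export
can_arena <- function(shape = c("circle", "square"), extent = 2) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(extent), length(extent) == 1L, extent > 0)
  structure(list(shape = shape, extent = extent), class = "can_arena")
}

#' @export
print.can_arena <- function(x, ...) {
  cat(sprintf("<can_arena> %s, extent %g m\n", x$shape, x$extent))
  invisible(x)
}

#' Test whether positions fall inside an arena
#'
#' @param arena A \code{\link{can_arena}}.
#' @param x,y Coordinates in metres (vectorised).
#' @return Logical vector.
#' @export
arena_contains <- function(arena, x, y) {
  stopifnot(inherits(arena, "can_arena"))
  if (arena$shape == "circle") {
    r <- arena$extent / 2
    (x - r)^2 + (y - r)^2 <= r^2
  } else {
    x >= 0 & x <= arena$extent & y >= 0 & y <= arena$extent
  }
}

#' Generate a virtual open-field trajectory
#'
#' Random-walk trajectory of a virtual animal designed to cover the arena
#' quickly. At each step a step length is drawn uniformly from
#' \code{[0, step_max]} and a heading increment uniformly from
#' \code{[-turn_halfwidth, turn_halfwidth]}; the increment is added to a
#' persistent absolute heading measured from the +y axis (x advances with the
#' sine of the heading, y with the cosine). Within \code{boundary_zone} of the
#' wall the absolute heading is redrawn uniformly from \code{[0, 2*pi)} so the
#' walk can turn sharply instead of stalling against the boundary. Candidate
#' positions falling outside the arena are rejected and redrawn.
#'
#' @param arena A \code{\link{can_arena}}.
#' @param duration Run duration in seconds.
#' @param dt_sample Sampling interval in seconds (default 1 ms, matching the
#'   network integration step).
#' @param seed Integer seed; identical seed and settings give a bitwise
#'   identical trajectory.
#' @param step_max Maximum step length in metres.
#' @param turn_halfwidth Half-width of the heading-increment distribution
#'   (radians).
#' @param boundary_zone Distance from the wall (metres) within which headings
#'   are redrawn uniformly; set to 0 for a plain incremental random walk with
#'   no boundary rule.
#' @param max_resample Cap on rejected draws per step before erroring.
#' @return A \code{can_trajectory}: list with numeric vectors \code{x},
#'   \code{y} (length \code{duration/dt_sample + 1}), and the generating
#'   settings.
#' @examples
#' tr <- generate_virtual_trajectory(can_arena(), duration = 1, seed = 1)
#' head(cbind(tr$x, tr$y))
#' @export
generate_virtual_trajectory <- function(arena = can_arena(), duration = 100,
                                        dt_sample = 0.001, seed = 1,
                                        step_max = 0.004,
                                        turn_halfwidth = pi / 36,
                                        boundary_zone = 0.02,
                                        max_resample = 1000) {
  stopifnot(inherits(arena, "can_arena"))
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be a positive number of seconds")
  }
  stopifnot(dt_sample > 0, step_max > 0, boundary_zone >= 0)
  n_steps <- as.integer(round(duration / dt_sample))
  pos <- with_seed(seed, trajectory_cpp(
    shape = if (arena$shape == "circle") 0L else 1L,
    extent = arena$extent, n_steps = n_steps, step_max = step_max,
    turn_halfwidth = turn_halfwidth, boundary_zone = boundary_zone,
    max_tries = as.integer(max_resample)))
  structure(list(x = pos[, 1], y = pos[, 2], dt_sample = dt_sample,
                 duration = duration, seed = seed, arena = arena,
                 step_max = step_max, turn_halfwidth = turn_halfwidth,
                 boundary_zone = boundary_zone),
            class = "can_trajectory")
}

#' @export
print.can_trajectory <- function(x, ...) {
  cat(sprintf("<can_trajectory> %d samples, dt = %g s, %s arena (%g m)\n",
              length(x$x), x$dt_sample, x$arena$shape, x$arena$extent))
  invisible(x)
}

#' Velocity series of a trajectory
#'
#' First differences of the positions. The network's feed-forward drive uses
#' per-step displacement (the default), which keeps the drive near its
#' operating point of 1 for the default velocity gain.
#'
#' @param traj A \code{can_trajectory}.
#' @param units \code{"per_step"} (displacement in metres per sample) or
#'   \code{"per_second"}.
#' @return A matrix with columns \code{vx}, \code{vy}, one row per trajectory
#'   sample; the first row is (0, 0).
#' @export
velocity_series <- function(traj, units = c("per_step", "per_second")) {
  units <- match.arg(units)
  stopifnot(inherits(traj, "can_trajectory"))
  n <- length(traj$x)
  if (n < 2L) stop("trajectory must have at least 2 samples")
  v <- cbind(vx = c(0, diff(traj$x)), vy = c(0, diff(traj$y)))
  if (units == "per_second") v <- v / traj$dt_sample
  v
}

# 1-based pixel index for each sample; pixel (1,1) is the corner at the
# origin, index runs x-fastest.
pixel_index <- function(x, y, extent, n_pixels) {
  w <- extent / n_pixels
  px <- pmin(pmax(floor(x / w), 0), n_pixels - 1)
  py <- pmin(pmax(floor(y / w), 0), n_pixels - 1)
  as.integer(py * n_pixels + px + 1)
}

# Logical matrix: which pixel centres are inside the arena.
arena_pixel_mask <- function(arena, n_pixels) {
  w <- arena$extent / n_pixels
  cx <- (seq_len(n_pixels) - 0.5) * w
  matrix(arena_contains(arena, rep(cx, n_pixels),
                        rep(cx, each = n_pixels)),
         nrow = n_pixels)
}

#' Fraction of the arena covered by a trajectory
#'
#' Divides the arena into \code{n_pixels x n_pixels} pixels and reports the
#' fraction of in-arena pixels visited at least once.
#'
#' @param traj A \code{can_trajectory}.
#' @param arena Arena (defaults to the trajectory's own).
#' @param n_pixels Pixels per axis.
#' @return Fraction in [0, 1].
#' @export
coverage_fraction <- function(traj, arena = traj$arena, n_pixels = 100) {
  stopifnot(inherits(traj, "can_trajectory"), n_pixels >= 1)
  idx <- pixel_index(traj$x, traj$y, arena$extent, n_pixels)
  mask <- arena_pixel_mask(arena, n_pixels)
  visited <- logical(n_pixels^2)
  visited[unique(idx)] <- TRUE
  sum(visited & as.vector(mask)) / sum(mask)
}

#' Write a trajectory to a CSV table
#'
#' Plain table with header \code{t,x,y} (seconds, metres).
#'
#' @param traj A \code{can_trajectory}.
#' @param path Output file path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "can_trajectory"))
  t <- seq(0, by = traj$dt_sample, length.out = length(traj$x))
  write.csv(data.frame(t = t, x = traj$x, y = traj$y), path,
            row.names = FALSE)
  invisible(path)
}

#' Load a trajectory from a CSV table
#'
#' Reads a table with columns \code{t}, \code{x}, \code{y} (seconds, metres),
#' e.g. a recorded animal path, and resamples it to a uniform sampling
#' interval by linear interpolation.
#'
#' @param path CSV file with header \code{t,x,y}.
#' @param dt_sample Target sampling interval in seconds (default 0.5 ms, the
#'   integration step used with recorded paths).
#' @param arena Arena the positions must lie in.
#' @return A \code{can_trajectory}.
#' @export
load_trajectory_table <- function(path, dt_sample = 0.0005,
                                  arena = can_arena()) {
  tab <- read.csv(path)
  if (!all(c("t", "x", "y") %in% names(tab))) {
    stop("trajectory table must have columns t, x, y")
  }
  if (nrow(tab) < 1L) stop("empty trajectory table")
  if (is.unsorted(tab$t, strictly = nrow(tab) > 1L)) {
    bad <- which(diff(tab$t) <= 0)[1] + 1L
    stop(sprintf("time column must be strictly increasing (row %d)", bad))
  }
  out <- !arena_contains(arena, tab$x, tab$y)
  if (any(out)) {
    stop(sprintf("positions outside the arena at rows: %s",
                 paste(which(out), collapse = ", ")))
  }
  if (nrow(tab) == 1L) {
    x <- tab$x; y <- tab$y
  } else {
    tt <- seq(tab$t[1], tab$t[nrow(tab)], by = dt_sample)
    x <- approx(tab$t, tab$x, xout = tt)$y
    y <- approx(tab$t, tab$y, xout = tt)$y
  }
  structure(list(x = x, y = y, dt_sample = dt_sample,
                 duration = (length(x) - 1L) * dt_sample, seed = NA_integer_,
                 arena = arena, step_max = NA_real_,
                 turn_halfwidth = NA_real_, boundary_zone = NA_real_),
            class = "can_trajectory")
}
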