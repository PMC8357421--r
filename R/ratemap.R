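# Spatial rate maps: occupancy-normalised mean activity per pixel, with
# masked Gaussian smoothing.

# Truncated-Gaussian band matrix used for separable smoothing along one
# axis. Rows are not normalised here; normalisation happens against the
# smoothed validity mask so arena edges are handled correctly.
smoothing_band <- function(n_pixels, sigma_px, trunc = 3) {
  key <- sprintf("smoothband_%d_%g_%g", n_pixels, sigma_px, trunc)
  cache_get_or(key, {
    r <- ceiling(trunc * sigma_px)
    d <- outer(seq_len(n_pixels), seq_len(n_pixels), "-")
    K <- exp(-d^2 / (2 * sigma_px^2))
    K[abs(d) > r] <- 0
    K
  })
}

# Mask-renormalised Gaussian smoothing of a map with invalid pixels.
smooth_masked <- function(values, valid, sigma_px, trunc = 3) {
  n <- nrow(values)
  K <- smoothing_band(n, sigma_px, trunc)
  V <- values
  V[!valid] <- 0
  num <- K %*% V %*% K
  den <- K %*% (valid * 1) %*% K
  out <- num / den
  out[!valid] <- NA_real_
  out
}

# Shared constructor from per-pixel activity sums and visit counts.
rate_map_from_counts <- function(act_sum, counts, arena, n_pixels,
                                 sigma_px = 2) {
  values <- matrix(NA_real_, n_pixels, n_pixels)
  counts_m <- matrix(counts, n_pixels, n_pixels)
  valid <- counts_m > 0
  values[valid] <- act_sum[as.vector(valid)] / counts_m[valid]
  p <- counts_m / sum(counts_m)
  structure(list(values = values, smoothed = smooth_masked(values, valid,
                                                           sigma_px),
                 occupancy = p, counts = counts_m, valid = valid,
                 arena = arena, n_pixels = as.integer(n_pixels),
                 sigma_px = sigma_px),
            class = "can_rate_map")
}

#' Spatial rate map of one neuron
#'
#' Accumulates the neuron's activity into \code{n_pixels x n_pixels} bins
#' over the arena, normalises by the per-pixel visit counts (mean activity
#' per visit), and smooths with a 2D Gaussian kernel (truncated at 3 sigma,
#' renormalised over valid pixels so unvisited bins do not bleed in).
#' Occupancy probabilities are visit counts over the total sample count.
#'
#' @param trace Either a \code{can_activity} from \code{\link{simulate_can}}
#'   or a numeric activity vector aligned with the trajectory samples.
#' @param neuron Neuron index (used when \code{trace} is a
#'   \code{can_activity}; it must be among the mapped or recorded neurons).
#' @param traj The trajectory the activity was simulated on (required when
#'   \code{trace} is a numeric vector).
#' @param trial Trial number for multi-trial activities.
#' @param arena Arena (defaults to the one stored with the inputs).
#' @param n_pixels Pixels per axis (default 100).
#' @param sigma_px Gaussian smoothing standard deviation in pixels.
#' @return An object of class \code{can_rate_map} with fields \code{values}
#'   (raw rate, NA where unvisited), \code{smoothed}, \code{occupancy},
#'   \code{counts} and \code{valid}. Matrices are indexed [x pixel, y pixel].
#' @export
compute_rate_map <- function(trace, neuron = NULL, traj = NULL, trial = 1,
                             arena = NULL, n_pixels = NULL, sigma_px = 2) {
  if (inherits(trace, "can_activity")) {
    act <- trace
    if (is.null(arena)) arena <- act$arena
    j <- match(neuron, act$map_neurons)
    if (!is.na(j) && (is.null(n_pixels) || n_pixels == act$n_pixels)) {
      return(rate_map_from_counts(act$act[[trial]][, j],
                                  act$occupancy_counts, arena,
                                  act$n_pixels, sigma_px))
    }
    j <- match(neuron, act$record_neurons)
    if (is.na(j)) stop("neuron was neither mapped nor recorded")
    if (is.null(traj)) stop("traj is required to re-bin a recorded trace")
    trace <- act$trace[[trial]][, j]
  }
  stopifnot(is.numeric(trace), inherits(traj, "can_trajectory"))
  if (length(trace) != length(traj$x)) {
    stop("activity series and trajectory have different lengths")
  }
  if (is.null(arena)) arena <- traj$arena
  if (is.null(n_pixels)) n_pixels <- 100
  pix <- pixel_index(traj$x, traj$y, arena$extent, n_pixels)
  act_sum <- numeric(n_pixels^2)
  sums <- rowsum(trace, pix)
  act_sum[as.integer(rownames(sums))] <- sums[, 1]
  counts <- tabulate(pix, nbins = n_pixels^2)
  rate_map_from_counts(act_sum, counts, arena, n_pixels, sigma_px)
}

#' @export
print.can_rate_map <- function(x, ...) {
  cat(sprintf(
    "<can_rate_map> %d x %d px, %d valid, peak %.3g, mean %.3g\n",
    x$n_pixels, x$n_pixels, sum(x$valid),
    max(x$smoothed, na.rm = TRUE), mean(x$values[x$valid])))
  invisible(x)
}

#' Rate maps for all mapped neurons of a simulation
#'
#' @param activity A \code{can_activity}.
#' @param neurons Subset of neuron indices (default: all mapped).
#' @param trial Trial number.
#' @param sigma_px Smoothing width in pixels.
#' @return Named list of \code{can_rate_map}, one per neuron.
#' @export
rate_maps <- function(activity, neurons = activity$map_neurons, trial = 1,
                      sigma_px = 2) {
  stopifnot(inherits(activity, "can_activity"))
  cols <- match(neurons, activity$map_neurons)
  if (anyNA(cols)) stop("some requested neurons were not mapped")
  maps <- lapply(cols, function(j) {
    rate_map_from_counts(activity$act[[trial]][, j],
                         activity$occupancy_counts, activity$arena,
                         activity$n_pixels, sigma_px)
  })
  names(maps) <- as.character(neurons)
  maps
}
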