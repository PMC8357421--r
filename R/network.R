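#' Network specification for the toroidal CAN lattice
#'
#' Collects the structural parameters of the grid-cell continuous attractor
#' network: an \code{n x n} sheet of neurons with periodic (toroidal)
#' boundaries, a 2x2 tiling of preferred directions, and centre-shifted
#' Mexican-hat (difference-of-Gaussians) recurrent weights. The DoG width
#' parameters are derived from the lattice periodicity \code{lambda_grid} as
#' \code{beta = 3 / lambda^2} and \code{gamma = 1.1 * beta}.
#'
#' @param n Lattice side (must be even; default 60, i.e. 3600 neurons).
#' @param lambda_grid Periodicity of the activity lattice in neurons.
#' @param shift Centre shift \code{l} of the outgoing weights along the
#'   presynaptic neuron's preferred direction, in lattice units.
#' @param a Sign/amplitude parameter of the DoG; \code{a = 1} gives an
#'   all-inhibitory network.
#' @param tau Default integration time constant in seconds.
#' @param alpha Default velocity scaling factor (gain on the per-step
#'   displacement in the feed-forward drive).
#' @return An object of class \code{can_network}.
#' @examples
#' net <- can_network(n = 40)
#' net$beta; net$gamma
#' @export
can_network <- function(n = 60, lambda_grid = 13, shift = 2, a = 1,
                        tau = 0.010, alpha = 45) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  if (n %% 2 != 0) stop("n must be even (2x2 direction blocks)")
  stopifnot(lambda_grid > 0, tau > 0)
  beta <- 3 / lambda_grid^2
  structure(list(n = as.integer(n), lambda_grid = lambda_grid,
                 shift = shift, a = a, tau = tau, alpha = alpha,
                 beta = beta, gamma = 1.1 * beta),
            class = "can_network")
}

#' @export
print.can_network <- function(x, ...) {
  cat(sprintf(
    "<can_network> %d x %d torus (%d neurons), lambda = %g, l = %g, a = %g\n",
    x$n, x$n, x$n^2, x$lambda_grid, x$shift, x$a))
  invisible(x)
}

#' Preferred-direction map of the lattice
#'
#' Tiles the lattice with 2x2 blocks of east/north/west/south preferring
#' neurons (block layout: E N / W S), so exactly one quarter of the neurons
#' share each preferred direction. Neuron \code{i} (1-based, column-fastest)
#' sits at lattice coordinate \code{(col, row) = ((i-1) \%\% n, (i-1) \%/\% n)}.
#'
#' @param n Lattice side (even).
#' @return A list with per-neuron \code{theta} (radians: 0, pi/2, pi, 3pi/2),
#'   direction index \code{dir} (0 = E, 1 = N, 2 = W, 3 = S), unit-vector
#'   components \code{ex}, \code{ey}, and \code{n}.
#' @export
build_preference_map <- function(n) {
  stopifnot(n >= 2)
  if (n %% 2 != 0) stop("n must be even")
  i <- seq_len(n^2) - 1L
  row <- i %/% n
  col <- i %% n
  # block layout [E N; W S] over (row parity, col parity)
  dir <- ifelse(row %% 2 == 0, ifelse(col %% 2 == 0, 0L, 1L),
                ifelse(col %% 2 == 0, 2L, 3L))
  ex <- c(1, 0, -1, 0)[dir + 1L]
  ey <- c(0, 1, 0, -1)[dir + 1L]
  list(theta = c(0, pi / 2, pi, 3 * pi / 2)[dir + 1L], dir = dir,
       ex = ex, ey = ey, n = as.integer(n))
}

#' Minimum-image displacement on the torus
#'
#' Component-wise difference \code{xi - xj} wrapped into \code{(-n/2, n/2]}.
#'
#' @param xi,xj Lattice coordinates: length-2 vectors or 2-column matrices.
#' @param n Lattice side.
#' @return Displacement vector(s), same shape as the inputs.
#' @export
toroidal_displacement <- function(xi, xj, n) {
  d <- xi - xj
  d <- d - n * floor(d / n)          # into [0, n)
  d[d > n / 2] <- d[d > n / 2] - n   # into (-n/2, n/2]
  d
}

#' Build the recurrent weight matrix
#'
#' Centre-shifted Mexican-hat weights on the torus:
#' \code{W[i, j] = W0(wrap(x_i - x_j) - l * e_hat(theta_j))} with
#' \code{W0(x) = a * exp(-gamma |x|^2) - exp(-beta |x|^2)}. For \code{a = 1}
#' every weight is non-positive (all-inhibitory network).
#'
#' @param spec A \code{\link{can_network}}.
#' @param prefs Preference map (defaults to \code{build_preference_map}).
#' @return Dense \code{n^2 x n^2} numeric matrix; entry (i, j) is the weight
#'   from neuron j onto neuron i.
#' @export
build_weight_matrix <- function(spec, prefs = build_preference_map(spec$n)) {
  stopifnot(inherits(spec, "can_network"))
  build_weights_cpp(n = spec$n, beta = spec$beta, gam = spec$gamma,
                    a = spec$a, l = spec$shift,
                    theta = as.integer(prefs$dir))
}

#' Root-mean-square difference between two weight matrices
#'
#' @param W_a,W_b Equal-shape numeric matrices.
#' @return \code{sqrt(mean((W_a - W_b)^2))} over all synapses.
#' @export
weight_rmse <- function(W_a, W_b) {
  if (!identical(dim(W_a), dim(W_b))) {
    stop("weight matrices must have identical shapes")
  }
  sqrt(mean((W_a - W_b)^2))
}
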