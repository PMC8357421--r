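#' Single-neuron dynamics model
#'
#' Three rate-based neuron models share the network equations and differ only
#' in their single-neuron dynamics:
#' \describe{
#'   \item{integrator}{leaky integrator, \code{tau dS/dt = -S + f(input)}
#'     with rectification \code{f(x) = max(x, 0)}; a low-pass filter.}
#'   \item{phenomenological}{the integrator's internal state \code{u} is
#'     passed through a high-pass stage: the emitted activity is
#'     \code{R * u * |du/dt|^epsilon}. \code{epsilon = 0}, \code{R = 1}
#'     reduces exactly to the integrator.}
#'   \item{mechanistic}{a slow activity-dependent negative feedback variable
#'     \code{m} with sigmoidal steady state
#'     \code{m_inf(S) = 1 / (1 + exp((S_half - S)/k))} and time constant
#'     \code{tau_m} is subtracted from the drive with strength \code{g}:
#'     \code{tau dS/dt = -S - g m + f(input)}. Resonance requires
#'     \code{tau_m > tau}. \code{g = 0} reduces exactly to the integrator.}
#' }
#'
#' @param kind One of \code{"integrator"}, \code{"phenomenological"},
#'   \code{"mechanistic"}.
#' @param tau Integration time constant in seconds.
#' @param epsilon High-pass exponent (phenomenological).
#' @param R Output scaling of the phenomenological resonator (default 1,
#'   which leaves the redefined activity on the scale of the underlying
#'   state and is the scaling under which resonator networks sustain the
#'   attractor; \code{\link{calibrate_R}} computes the alternative
#'   chirp-magnitude-matching value for single-neuron comparisons).
#' @param deriv How the fractional power of the derivative is taken:
#'   \code{"magnitude"} uses |du/dt| (default; a fractional power of a
#'   negative number is undefined), \code{"rectified"} uses max(du/dt, 0).
#' @param deriv_tau Time constant (seconds) of an exponential moving
#'   average applied to du/dt inside the network loop before the
#'   fractional power; 0 (default for single neurons) uses the raw
#'   per-step difference. In trajectory-driven networks the per-step
#'   feed-forward drive is noisy (the walk resamples its speed every
#'   step), and an unsmoothed derivative hands that noise straight to the
#'   recurrent input.
#' @param recurrence Whether other neurons see the \code{"redefined"} output
#'   (default) or the \code{"internal"} low-pass state u.
#' @param g Feedback strength (mechanistic).
#' @param k Slope of the feedback kernel (mechanistic).
#' @param S_half Half-maximal activity of the feedback kernel (mechanistic).
#' @param tau_m Feedback time constant in seconds (mechanistic).
#' @return An object of class \code{can_neuron_model}.
#' @examples
#' neuron_model("phenomenological", tau = 0.010, epsilon = 0.3, R = 1)
#' @export
neuron_model <- function(kind = c("integrator", "phenomenological",
                                  "mechanistic"),
                         tau = 0.010, epsilon = 0.3, R = 1,
                         deriv = c("magnitude", "rectified"),
                         recurrence = c("redefined", "internal"),
                         deriv_tau = 0,
                         g = 0.015, k = 0.1, S_half = 0.3, tau_m = 0.075) {
  kind <- match.arg(kind)
  deriv <- match.arg(deriv)
  recurrence <- match.arg(recurrence)
  stopifnot(tau > 0, epsilon >= 0, tau_m > 0, k > 0, deriv_tau >= 0)
  if (is.null(R)) R <- calibrate_R(tau = tau, epsilon = epsilon,
                                   deriv = deriv)
  structure(list(kind = kind, tau = tau, epsilon = epsilon, R = R,
                 deriv = deriv, recurrence = recurrence,
                 deriv_tau = deriv_tau, g = g, k = k,
                 S_half = S_half, tau_m = tau_m),
            class = "can_neuron_model")
}

#' @export
print.can_neuron_model <- function(x, ...) {
  extra <- switch(x$kind,
    integrator = "",
    phenomenological = sprintf(", epsilon = %g, R = %.4g", x$epsilon, x$R),
    mechanistic = sprintf(", g = %g, k = %g, S_half = %g, tau_m = %g s",
                          x$g, x$k, x$S_half, x$tau_m))
  cat(sprintf("<can_neuron_model> %s, tau = %g s%s\n", x$kind, x$tau, extra))
  invisible(x)
}

.kind_code <- function(kind) {
  match(kind, c("integrator", "phenomenological", "mechanistic")) - 1L
}

#' Simulation configuration
#'
#' @param dt Integration step in seconds (1 ms for virtual trajectories,
#'   0.5 ms recommended for recorded paths). Must equal the trajectory's
#'   sampling interval.
#' @param settle Zero-velocity settling period in seconds run before the
#'   trajectory drive starts (excluded from all analyses).
#' @param init_seed Integer seed(s) for the uniform [0, 1] initial
#'   activities. A vector runs one trial per seed; trials share the weight
#'   matrix, trajectory and heterogeneity instance.
#' @param record_neurons Neuron indices whose full-resolution activity is
#'   returned, or \code{"all"}.
#' @param map_neurons Neuron indices whose spatial activity is accumulated
#'   into per-pixel sums, or \code{"all"} (default).
#' @param n_pixels Pixels per axis for the spatial accumulation.
#' @param record_m Also record the feedback state m (mechanistic model).
#' @return An object of class \code{can_sim_config}.
#' @export
sim_config <- function(dt = 0.001, settle = 0.100, init_seed = 1,
                       record_neurons = integer(0), map_neurons = "all",
                       n_pixels = 100, record_m = FALSE) {
  stopifnot(dt > 0, settle >= 0, n_pixels >= 1)
  structure(list(dt = dt, settle = settle, init_seed = init_seed,
                 record_neurons = record_neurons, map_neurons = map_neurons,
                 n_pixels = as.integer(n_pixels), record_m = record_m),
            class = "can_sim_config")
}
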