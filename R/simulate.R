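#' Feed-forward velocity drive
#'
#' Per-neuron afferent drive \code{B_i = 1 + alpha_i * (e_hat_i . v)}, where
#' \code{e_hat_i} is the neuron's preferred-direction unit vector and
#' \code{v} the animal's per-step displacement.
#'
#' @param prefs Preference map from \code{\link{build_preference_map}}.
#' @param alpha_i Per-neuron velocity gain (recycled if scalar).
#' @param v Length-2 velocity vector (per-step displacement, metres).
#' @return Numeric vector of drives, one per neuron.
#' @export
feedforward_drive <- function(prefs, alpha_i, v) {
  stopifnot(length(v) == 2L, all(is.finite(v)))
  1 + alpha_i * (prefs$ex * v[1] + prefs$ey * v[2])
}

#' One forward-Euler step of the integrator network
#'
#' \code{S' = S + (dt / tau_i) * (-S + f(W S + B))} with rectification
#' \code{f(x) = max(x, 0)}. Reference R implementation used for validating
#' the compiled integration loop; \code{\link{simulate_can}} is the fast
#' path.
#'
#' @param S Activity vector.
#' @param W Recurrent weight matrix.
#' @param B Feed-forward drive vector.
#' @param tau_i Per-neuron time constants (seconds; recycled if scalar).
#' @param dt Step in seconds.
#' @return Updated activity vector.
#' @export
step_integrator <- function(S, W, B, tau_i, dt) {
  if (any(!is.finite(S)) || any(!is.finite(B))) {
    stop("non-finite values in the network state or drive")
  }
  drive <- pmax(as.vector(W %*% S) + B, 0)
  S + (dt / tau_i) * (drive - S)
}

#' One step of the phenomenological resonator network
#'
#' The internal state follows the integrator dynamics; the emitted activity
#' is \code{R * u * |du/dt|^epsilon}.
#'
#' @param state List with internal state \code{u} and emitted activity
#'   \code{S} (what the recurrent sum consumed last step).
#' @param W,B,tau_i,dt As in \code{\link{step_integrator}}.
#' @param epsilon High-pass exponent.
#' @param R Output scaling.
#' @param deriv \code{"magnitude"} or \code{"rectified"}.
#' @param recurrence \code{"redefined"} or \code{"internal"}.
#' @return List with updated \code{state} and the emitted \code{S_out}.
#' @export
step_phenomenological <- function(state, W, B, tau_i, epsilon, R, dt,
                                  deriv = "magnitude",
                                  recurrence = "redefined") {
  u <- state$u
  pre <- if (recurrence == "internal") u else state$S
  drive <- pmax(as.vector(W %*% pre) + B, 0)
  u_new <- u + (dt / tau_i) * (drive - u)
  du <- (u_new - u) / dt
  dpart <- if (deriv == "rectified") pmax(du, 0) else abs(du)
  S_out <- R * u_new * dpart^epsilon
  list(state = list(u = u_new, S = S_out), S_out = S_out)
}

#' One step of the mechanistic resonator network
#'
#' \code{S' = S + (dt / tau_i) * (-S - g m + f(W S + B))};
#' \code{m' = m + (dt / tau_m) * (m_inf(S) - m)} with
#' \code{m_inf(S) = 1 / (1 + exp((S_half - S) / k))}.
#'
#' @param S,W,B,tau_i,dt As in \code{\link{step_integrator}}.
#' @param m Feedback state vector.
#' @param g Feedback strength.
#' @param k Feedback kernel slope.
#' @param S_half Half-maximal activity of the feedback kernel.
#' @param tau_m Feedback time constant (seconds).
#' @return List with updated \code{S} and \code{m}.
#' @export
step_mechanistic <- function(S, m, W, B, tau_i, g, k, S_half, tau_m, dt) {
  if (any(!is.finite(S)) || any(!is.finite(B))) {
    stop("non-finite values in the network state or drive")
  }
  drive <- pmax(as.vector(W %*% S) + B, 0)
  S_new <- S + (dt / tau_i) * (-S - g * m + drive)
  m_new <- m + (dt / tau_m) * (m_inf(S, S_half, k) - m)
  list(S = S_new, m = m_new)
}

#' Steady-state feedback kernel of the mechanistic resonator
#'
#' @param S Activity.
#' @param S_half Half-maximal activity.
#' @param k Slope.
#' @return \code{1 / (1 + exp((S_half - S) / k))}.
#' @export
m_inf <- function(S, S_half = 0.3, k = 0.1) {
  1 / (1 + exp((S_half - S) / k))
}

#' Simulate the CAN network along a trajectory
#'
#' Integrates the network with forward Euler at the trajectory's sampling
#' interval. Initial activities are drawn uniformly from [0, 1] per trial
#' seed; the mechanistic feedback state starts at its steady state. A
#' zero-velocity settling period precedes the trajectory drive and is
#' excluded from all returned series. Activities are aligned one row per
#' trajectory sample (row 1 is the settled state at the starting position).
#'
#' @param network A \code{\link{can_network}}.
#' @param assignment A \code{\link{apply_heterogeneities}} result; NULL
#'   builds the homogeneous assignment (degree 0) from \code{network}.
#' @param traj A \code{\link{generate_virtual_trajectory}} result.
#' @param model A \code{\link{neuron_model}}.
#' @param cfg A \code{\link{sim_config}}. \code{cfg$dt} must equal
#'   \code{traj$dt_sample}.
#' @return An object of class \code{can_activity}: per-trial activity traces
#'   for the recorded neurons, per-pixel activity sums and occupancy counts
#'   for the mapped neurons, the settled and final network states, and the
#'   alignment metadata the analysis functions need.
#' @export
simulate_can <- function(network, assignment = NULL, traj,
                         model = neuron_model("integrator",
                                              tau = network$tau),
                         cfg = sim_config()) {
  stopifnot(inherits(network, "can_network"),
            inherits(traj, "can_trajectory"),
            inherits(model, "can_neuron_model"),
            inherits(cfg, "can_sim_config"))
  if (abs(cfg$dt - traj$dt_sample) > 1e-12) {
    stop("cfg$dt must equal the trajectory sampling interval")
  }
  if (is.null(assignment)) {
    assignment <- apply_heterogeneities(network,
                                        build_weight_matrix(network),
                                        het_spec(degree = 0))
  }
  stopifnot(inherits(assignment, "can_het_assignment"))
  N <- network$n^2
  if (max(cfg$dt / assignment$tau_i) > 1 + 1e-9) {
    stop("Euler stability requires dt <= tau for every neuron")
  }
  if (max(cfg$dt / assignment$tau_i) > 0.5 + 1e-9) {
    # dt/tau in (0.5, 1] is stable but coarse for the fastest neurons
    warning("dt/tau exceeds 0.5 for some neurons; integration is coarse")
  }

  prefs <- build_preference_map(network$n)
  v <- velocity_series(traj, units = "per_step")
  idx_arg <- function(sel) {
    if (identical(sel, "all")) seq_len(N) else as.integer(sel)
  }
  record_idx <- idx_arg(cfg$record_neurons)
  map_idx <- idx_arg(cfg$map_neurons)
  stopifnot(all(record_idx >= 1 & record_idx <= N),
            all(map_idx >= 1 & map_idx <= N))

  pix <- pixel_index(traj$x, traj$y, traj$arena$extent, cfg$n_pixels)
  seeds <- as.integer(cfg$init_seed)
  S0 <- vapply(seeds, function(s) with_seed(s, runif(N)), numeric(N))

  res <- simulate_cpp(
    W_ = assignment$W, S0_ = S0, kind = .kind_code(model$kind),
    tau = assignment$tau_i, alpha = assignment$alpha_i,
    ex = prefs$ex, ey = prefs$ey, vx = v[, 1], vy = v[, 2],
    dt = cfg$dt, settle_steps = as.integer(round(cfg$settle / cfg$dt)),
    epsilon = model$epsilon, Rscale = model$R,
    recur_internal = identical(model$recurrence, "internal"),
    deriv_tau = if (is.null(model$deriv_tau)) 0 else model$deriv_tau,
    g = model$g, kslope = model$k, S_half = model$S_half,
    tau_m = model$tau_m,
    record_idx = record_idx - 1L, map_idx = map_idx - 1L,
    pix = pix - 1L, n_pix = cfg$n_pixels^2,
    record_m = isTRUE(cfg$record_m))

  counts <- tabulate(pix, nbins = cfg$n_pixels^2)
  structure(list(
    trace = res$trace, act = res$act,
    m_trace = if (isTRUE(cfg$record_m)) res$m_trace else NULL,
    S_settled = res$S_settled, S_final = res$S_final,
    occupancy_counts = counts, record_neurons = record_idx,
    map_neurons = map_idx, n_pixels = cfg$n_pixels, dt = cfg$dt,
    n_trials = length(seeds), init_seed = seeds,
    arena = traj$arena, network = network, model = model,
    het = assignment$het), class = "can_activity")
}

#' @export
print.can_activity <- function(x, ...) {
  cat(sprintf(
    "<can_activity> %s model, %d trial(s), %d recorded / %d mapped neurons\n",
    x$model$kind, x$n_trials, length(x$record_neurons),
    length(x$map_neurons)))
  invisible(x)
}
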