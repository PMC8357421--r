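# Reproducible experiment orchestration: one call builds the trajectory,
# network, heterogeneity instance, simulates the heterogeneous network and
# its homogeneous twin on identical inputs, and derives metrics and spectra.

#' Experiment configuration
#'
#' Bundles everything one experiment needs. Every random draw is traceable
#' to one of three named seeds: \code{trajectory}, \code{init} (initial
#' activities; a vector runs one trial per seed) and \code{het}
#' (heterogeneity instance).
#'
#' @param network A \code{\link{can_network}}.
#' @param model A \code{\link{neuron_model}}.
#' @param het A \code{\link{het_spec}} (its seed is overridden by
#'   \code{seeds$het}).
#' @param arena Arena for the virtual trajectory.
#' @param duration Trajectory duration in seconds.
#' @param dt Integration/sampling step in seconds.
#' @param seeds Named list with \code{trajectory}, \code{init} (scalar or
#'   vector) and \code{het}.
#' @param n_pixels Rate-map resolution per axis.
#' @param map_neurons Neuron indices whose rate maps/metrics are computed,
#'   or \code{"all"}.
#' @param record_neurons Neuron indices whose full-resolution traces feed
#'   the spectral analysis, or \code{"all"}; \code{integer(0)} disables
#'   spectra.
#' @param settle Settling period in seconds.
#' @param compute_fields Also run field detection per neuron (slower).
#' @param sigma_px Rate-map smoothing width in pixels.
#' @return An object of class \code{can_experiment_config}.
#' @export
experiment_config <- function(network = can_network(), model =
                                neuron_model("integrator",
                                             tau = network$tau),
                              het = het_spec(degree = 0),
                              arena = can_arena(), duration = 100,
                              dt = 0.001,
                              seeds = list(trajectory = 1, init = 1,
                                           het = 1),
                              n_pixels = 100, map_neurons = "all",
                              record_neurons = integer(0), settle = 0.100,
                              compute_fields = FALSE, sigma_px = 2) {
  stopifnot(inherits(network, "can_network"),
            inherits(model, "can_neuron_model"),
            inherits(het, "can_het_spec"),
            all(c("trajectory", "init", "het") %in% names(seeds)))
  structure(list(network = network, model = model, het = het,
                 arena = arena, duration = duration, dt = dt, seeds = seeds,
                 n_pixels = as.integer(n_pixels),
                 map_neurons = map_neurons,
                 record_neurons = record_neurons, settle = settle,
                 compute_fields = compute_fields, sigma_px = sigma_px),
            class = "can_experiment_config")
}

# Metrics table for one simulated trial, vectorised over the mapped neurons.
trial_metrics <- function(activity, trial, sigma_px, compute_fields) {
  np <- activity$n_pixels
  counts <- activity$occupancy_counts
  valid <- counts > 0
  p <- counts / sum(counts)
  A <- activity$act[[trial]]
  Rate <- sweep(A, 1L, pmax(counts, 1L), "/")
  Rate[!valid, ] <- 0
  Ssm <- cache_get_or(sprintf("smoothop_%d_%g", np, sigma_px), {
    Ks <- Matrix::Matrix(smoothing_band(np, sigma_px), sparse = TRUE)
    Matrix::kronecker(Ks, Ks)
  })
  den <- as.vector(Ssm %*% (valid * 1))
  Sm <- as.matrix(Ssm %*% Rate) / den
  Sm[!valid, ] <- 0
  gs <- grid_score_batch(Sm, valid, np,
                         circular_mask = activity$arena$shape == "square")
  mu <- colSums(Rate[valid, , drop = FALSE]) / sum(valid)
  mu_w <- colSums(p[valid] * Rate[valid, , drop = FALSE])
  msq <- colSums(p[valid] * Rate[valid, , drop = FALSE]^2)
  info <- vapply(seq_len(ncol(Rate)), function(j) {
    r <- Rate[valid, j]
    m <- mu_w[j]
    if (m <= 0) return(0)
    nz <- r > 0
    sum(p[valid][nz] * r[nz] * log2(r[nz] / m))
  }, numeric(1))
  out <- data.frame(neuron = activity$map_neurons, trial = trial,
                    grid_score = gs$score, avg_rate = mu,
                    peak_rate = apply(Sm, 2L, max),
                    n_fields = NA_integer_,
                    mean_field_size_px = NA_real_,
                    avg_spacing_px = NA_real_,
                    info_rate_bits_s = info,
                    sparsity = ifelse(msq > 0, mu_w^2 / msq, NA_real_))
  if (compute_fields) {
    for (j in seq_along(activity$map_neurons)) {
      map <- rate_map_from_counts(A[, j], counts, activity$arena, np,
                                  sigma_px)
      fl <- detect_fields(map)
      nf <- nrow(fl$peaks)
      out$n_fields[j] <- nf
      out$mean_field_size_px[j] <- if (nf > 0) sum(fl$areas) / nf else 0
      if (nf >= 2L) {
        d <- dist(fl$peaks[, c("px", "py")])
        out$avg_spacing_px[j] <- mean(d)
      }
    }
  }
  out
}

#' Run one paired heterogeneous/homogeneous experiment
#'
#' Generates the virtual trajectory, builds the network and the requested
#' heterogeneity instance, simulates the heterogeneous network and its
#' homogeneous twin with identical trajectory and initial conditions, and
#' derives grid metrics, per-neuron percent changes, and (when trace
#' recording is enabled) spectra, normalised spectral differences, variance
#' profiles and octave shares. With heterogeneity degree 0 the "twin" is
#' the same simulation and all percent changes are zero.
#'
#' @param config An \code{\link{experiment_config}}.
#' @param out_dir Optional directory; when given, metrics tables (CSV) and
#'   a manifest (JSON) sufficient to re-run the experiment are written.
#' @return An object of class \code{can_result_bundle}: \code{metrics_het},
#'   \code{metrics_homo}, \code{percent_change} (data frames), optional
#'   \code{spectral} summaries, the simulations and the config.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "can_experiment_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  traj <- stage("trajectory", generate_virtual_trajectory(
    config$arena, duration = config$duration, dt_sample = config$dt,
    seed = config$seeds$trajectory))
  W <- stage("network", build_weight_matrix(config$network))
  het <- config$het
  het$seed <- config$seeds$het
  asg_het <- stage("heterogeneity",
                   apply_heterogeneities(config$network, W, het))
  asg_homo <- apply_heterogeneities(config$network, W, het_spec(degree = 0))
  cfg <- sim_config(dt = config$dt, settle = config$settle,
                    init_seed = config$seeds$init,
                    record_neurons = config$record_neurons,
                    map_neurons = config$map_neurons,
                    n_pixels = config$n_pixels)
  homogeneous <- het$degree == 0
  sim_het <- stage("simulate", simulate_can(config$network, asg_het, traj,
                                            config$model, cfg))
  sim_homo <- if (homogeneous) sim_het else {
    stage("simulate_twin", simulate_can(config$network, asg_homo, traj,
                                        config$model, cfg))
  }

  n_trials <- sim_het$n_trials
  mt_het <- do.call(rbind, lapply(seq_len(n_trials), function(k) {
    trial_metrics(sim_het, k, config$sigma_px, config$compute_fields)
  }))
  mt_homo <- do.call(rbind, lapply(seq_len(n_trials), function(k) {
    trial_metrics(sim_homo, k, config$sigma_px, config$compute_fields)
  }))
  pc <- mt_het
  num_cols <- setdiff(names(pc), c("neuron", "trial"))
  for (cn in num_cols) pc[[cn]] <- percent_change(mt_het[[cn]],
                                                  mt_homo[[cn]])

  spectral <- NULL
  if (length(config$record_neurons) > 0) {
    spectral <- lapply(seq_len(n_trials), function(k) {
      sp_het <- activity_spectrum(sim_het$trace[[k]], config$dt, f_max = 50)
      sp_homo <- activity_spectrum(sim_homo$trace[[k]], config$dt,
                                   f_max = 50)
      cmpr <- normalized_spectral_difference(sp_het, sp_homo)
      vp <- variance_profile(cmpr)
      list(spectrum_het = sp_het, spectrum_homo = sp_homo,
           comparison = cmpr, variance = vp,
           variance_total_auc = trapz_int(cmpr$freqs, vp),
           variance_octaves = octave_auc(vp, cmpr$freqs),
           magnitude_octaves_het = octave_auc(sp_het))
    })
  }
  bundle <- structure(list(config = config, trajectory = traj,
                           metrics_het = mt_het, metrics_homo = mt_homo,
                           percent_change = pc, spectral = spectral,
                           sim_het = sim_het, sim_homo = sim_homo),
                      class = "can_result_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write an experiment bundle to disk
#'
#' Metrics tables as CSV and a JSON manifest (all seeds and parameters)
#' sufficient to reproduce the run.
#'
#' @param bundle A \code{\link{run_experiment}} result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "can_result_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$metrics_het, file.path(dir, "metrics_het.csv"),
            row.names = FALSE)
  write.csv(bundle$metrics_homo, file.path(dir, "metrics_homo.csv"),
            row.names = FALSE)
  write.csv(bundle$percent_change, file.path(dir, "percent_change.csv"),
            row.names = FALSE)
  cfg <- bundle$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("gridcan")),
    network = unclass(cfg$network), model = unclass(cfg$model),
    het = unclass(cfg$het), arena = unclass(cfg$arena),
    duration = cfg$duration, dt = cfg$dt, seeds = cfg$seeds,
    n_pixels = cfg$n_pixels, settle = cfg$settle)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Named experiment presets
#'
#' Configurations mirroring the study's experiment families at a chosen
#' scale: heterogeneity sweeps (combined and per kind), resonator rescue
#' (phenomenological and mechanistic), the feedback-time-constant sweep,
#' integration-time-constant and high-pass-exponent sweeps, and a
#' network-size sweep. Each preset is a list of
#' \code{\link{experiment_config}} objects sharing the trajectory seed so
#' runs are directly comparable.
#'
#' @param n Lattice side for the presets.
#' @param duration Trajectory duration in seconds.
#' @param trials Number of trials (initial-condition seeds) per run.
#' @param seeds Base named seeds (see \code{\link{experiment_config}}).
#' @param n_pixels Rate-map resolution.
#' @return Named list of preset families; each family is a named list of
#'   \code{can_experiment_config}.
#' @export
can_presets <- function(n = 40, duration = 100, trials = 3,
                        seeds = list(trajectory = 1, init = NULL, het = 1),
                        n_pixels = 100) {
  if (is.null(seeds$init)) seeds$init <- seq_len(trials)
  base <- function(model, het = het_spec(degree = 0), net = can_network(n)) {
    experiment_config(network = net, model = model, het = het,
                      duration = duration, seeds = seeds,
                      n_pixels = n_pixels)
  }
  integ <- function(net = can_network(n)) {
    neuron_model("integrator", tau = net$tau)
  }
  phen <- function() neuron_model("phenomenological")
  mech <- function(tau_m = 0.075) neuron_model("mechanistic", tau_m = tau_m)
  deg_list <- function(model, kinds = "all") {
    setNames(lapply(1:5, function(d) {
      base(model, het_spec(kinds = kinds, degree = d))
    }), paste0("degree", 1:5))
  }
  list(
    heterogeneity_sweep = deg_list(integ()),
    heterogeneity_by_kind = setNames(lapply(
      c("intrinsic", "afferent", "synaptic"), function(kind) {
        base(integ(), het_spec(kinds = kind, degree = 3))
      }), c("intrinsic", "afferent", "synaptic")),
    resonator_rescue_phenomenological = deg_list(phen()),
    resonator_rescue_mechanistic = deg_list(mech()),
    tau_m_sweep = setNames(lapply(c(0.005, 0.015, 0.025, 0.050, 0.075),
                                  function(tm) {
      base(mech(tm), het_spec(degree = 5))
    }), paste0("tau_m_", c(5, 15, 25, 50, 75), "ms")),
    tau_sweep = setNames(lapply(c(0.008, 0.010, 0.014), function(tau) {
      net <- can_network(n, tau = tau)
      base(neuron_model("phenomenological", tau = tau), net = net)
    }), paste0("tau_", c(8, 10, 14), "ms")),
    epsilon_sweep = setNames(lapply(c(0.1, 0.3, 0.5), function(eps) {
      base(neuron_model("phenomenological", epsilon = eps))
    }), paste0("epsilon_", c(0.1, 0.3, 0.5))),
    network_size_sweep = setNames(lapply(c(40, 50, 60, 80), function(nn) {
      base(integ(can_network(nn)), net = can_network(nn))
    }), paste0("n", c(40, 50, 60, 80))))
}
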