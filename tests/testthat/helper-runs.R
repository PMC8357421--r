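# Shared heavy simulations for the network-level tests. Runs are cached in
# a session-level environment so every test file sees the same objects
# regardless of execution order, and each simulation happens once.
#
# Desk scale (documented in the methods vignette): 48 x 48 lattice (the
# smallest torus sustaining stable hexagonal patterns), 20 s trajectories,
# 50 x 50 px maps, metrics on a 96-neuron subset, spectra on an 80-neuron
# subset, two trials per condition; 60 x 60 for the scaled-down full-size
# collapse check.

TEST_N <- 48L
TEST_DURATION <- 20
TEST_PIXELS <- 50L
TRIAL_SEEDS <- c(11L, 12L)
HET_SEED <- 7L
TRAJ_SEED <- 42L

.heavy_cache <- new.env(parent = emptyenv())

heavy_get <- function(key, expr) {
  if (!exists(key, envir = .heavy_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .heavy_cache)
  }
  get(key, envir = .heavy_cache, inherits = FALSE)
}

shared_traj <- function(duration = TEST_DURATION) {
  heavy_get(sprintf("traj_%g", duration), {
    generate_virtual_trajectory(can_arena("circle", 2),
                                duration = duration, seed = TRAJ_SEED)
  })
}

shared_W <- function(n = TEST_N) {
  heavy_get(sprintf("W_%d", n), build_weight_matrix(can_network(n = n)))
}

map_subset <- function(n) as.integer(round(seq(1, n^2, length.out = 96)))
rec_subset <- function(n) as.integer(round(seq(7, n^2, length.out = 80)))

# One cached network run: simulate, per-trial metrics on the map subset,
# spectrum of the recorded subset (trial 1), without keeping raw traces.
net_run <- function(kind, degree = 0, het_kinds = "all", tau_m = 0.075,
                    n = TEST_N, trials = TRIAL_SEEDS,
                    duration = TEST_DURATION, spectra = FALSE,
                    metrics = TRUE) {
  key <- sprintf("run_%s_d%s_%s_tm%g_n%d_K%d_T%g_sp%d_me%d", kind, degree,
                 paste(het_kinds, collapse = "+"), tau_m, n,
                 length(trials), duration, spectra, metrics)
  heavy_get(key, {
    net <- can_network(n = n)
    asg <- apply_heterogeneities(
      net, shared_W(n),
      het_spec(kinds = het_kinds, degree = degree, seed = HET_SEED))
    model <- switch(kind,
      integrator = neuron_model("integrator", tau = net$tau),
      phenomenological = neuron_model("phenomenological"),
      mechanistic = neuron_model("mechanistic", tau_m = tau_m))
    cfg <- sim_config(
      init_seed = trials,
      map_neurons = if (metrics) map_subset(n) else integer(0),
      record_neurons = if (spectra) rec_subset(n) else integer(0),
      n_pixels = TEST_PIXELS)
    sim <- suppressWarnings(simulate_can(net, asg, shared_traj(duration),
                                         model, cfg))
    out <- list(kind = kind, degree = degree, n = n)
    if (metrics) {
      out$metrics <- do.call(rbind, lapply(seq_along(trials), function(k) {
        gridcan:::trial_metrics(sim, k, 2, FALSE)
      }))
    }
    if (spectra) {
      out$spectrum <- activity_spectrum(sim$trace[[1]], sim$dt, f_max = 50)
    }
    out$S_settled <- sim$S_settled[, 1]
    out
  })
}

# Median grid-score percent change of a run against its homogeneous twin
# (same model family, same trials).
median_rescue <- function(run, twin) {
  stopifnot(nrow(run$metrics) == nrow(twin$metrics))
  pc <- percent_change(run$metrics$grid_score, twin$metrics$grid_score)
  median(pc, na.rm = TRUE)
}

# Variance profile of the paired spectral comparison and its summaries.
variance_auc <- function(run_het, run_homo) {
  cmpr <- normalized_spectral_difference(run_het$spectrum,
                                         run_homo$spectrum)
  vp <- variance_profile(cmpr)
  list(total = gridcan:::trapz_int(cmpr$freqs, vp),
       octaves = octave_auc(vp, cmpr$freqs),
       profile = vp, freqs = cmpr$freqs)
}
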