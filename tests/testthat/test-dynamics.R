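# Small networks exercise the integration step logic; the R step functions
# serve as the independent oracle for the compiled loop.

tiny_setup <- function(n = 4, tau = 0.01, alpha = 45) {
  net <- can_network(n = n, tau = tau, alpha = alpha)
  W <- build_weight_matrix(net)
  asg <- apply_heterogeneities(net, W, het_spec(degree = 0))
  prefs <- build_preference_map(n)
  list(net = net, W = W, asg = asg, prefs = prefs)
}

straight_traj <- function(n_steps, v = c(0.002, 0), dt = 0.001) {
  structure(list(x = cumsum(c(1, rep(v[1], n_steps))),
                 y = cumsum(c(1, rep(v[2], n_steps))),
                 dt_sample = dt, duration = n_steps * dt, seed = 0,
                 arena = can_arena("square", 1e6), step_max = 0.004,
                 turn_halfwidth = pi / 36, boundary_zone = 0),
            class = "can_trajectory")
}

test_that("feed-forward drive follows the direction-tuned gain", {
  prefs <- build_preference_map(4)
  expect_equal(feedforward_drive(prefs, 45, c(0, 0)), rep(1, 16))
  B <- feedforward_drive(prefs, 45, c(0.002, 0))
  expect_equal(B[prefs$dir == 0], rep(1.09, 4))   # east-preferring
  expect_equal(B[prefs$dir == 2], rep(0.91, 4))   # west-preferring
  expect_equal(B[prefs$dir == 1], rep(1, 4))      # orthogonal
})

test_that("integrator step implements rectified leaky Euler updates", {
  W0 <- matrix(0, 2, 2)
  # zero total input: pure decay by dt/tau
  expect_equal(step_integrator(c(1, 1), W0, c(0, 0), 0.01, 0.001),
               c(0.9, 0.9))
  # negative drive is rectified to zero -> same pure decay
  expect_equal(step_integrator(c(1, 1), W0, c(-5, -2), 0.01, 0.001),
               c(0.9, 0.9))
  # a fixed point S = f(WS + B) is preserved
  expect_equal(step_integrator(c(2, 3), W0, c(2, 3), 0.01, 0.001), c(2, 3))
  expect_error(step_integrator(c(NaN, 1), W0, c(0, 0), 0.01, 0.001),
               "non-finite")
})

test_that("resonator steps reduce to the integrator at the limit settings", {
  s <- tiny_setup()
  set.seed(1)
  S <- runif(16)
  B <- feedforward_drive(s$prefs, 45, c(0.002, 0.001))
  # phenomenological with eps = 0, R = 1
  ph <- step_phenomenological(list(u = S, S = S), s$W, B, 0.01,
                              epsilon = 0, R = 1, dt = 0.001)
  expect_equal(ph$S_out, step_integrator(S, s$W, B, 0.01, 0.001))
  # mechanistic with g = 0
  mech <- step_mechanistic(S, m_inf(S), s$W, B, 0.01, g = 0, k = 0.1,
                           S_half = 0.3, tau_m = 0.075, dt = 0.001)
  expect_equal(mech$S, step_integrator(S, s$W, B, 0.01, 0.001))
  # constant u gives zero output for eps > 0
  u0 <- rep(0.5, 16)
  ph2 <- step_phenomenological(list(u = u0, S = u0), matrix(0, 16, 16),
                               rep(0.5, 16), 1e6, epsilon = 0.3, R = 1,
                               dt = 0.001)
  expect_equal(ph2$S_out, rep(0, 16))
  # sigmoid midpoint of the feedback kernel
  expect_equal(m_inf(0.3, 0.3, 0.1), 0.5)
})

test_that("mechanistic steady state matches a root-finding oracle", {
  # single neuron, constant input I, no recurrence
  I <- 0.8; g <- 0.4; k <- 0.1; S_half <- 0.3
  f_root <- function(S) S - (I - g * m_inf(S, S_half, k))
  S_star <- uniroot(f_root, c(-1, 2), tol = 1e-12)$root
  S <- 0; m <- m_inf(0, S_half, k)
  W1 <- matrix(0, 1, 1)
  for (t in 1:20000) {
    st <- step_mechanistic(S, m, W1, I, 0.01, g, k, S_half, 0.075, 0.001)
    S <- st$S; m <- st$m
  }
  expect_equal(S, S_star, tolerance = 1e-6)
})

test_that("compiled network loop agrees with the R step oracles", {
  s <- tiny_setup()
  traj <- straight_traj(20)
  for (kind in c("integrator", "phenomenological", "mechanistic")) {
    model <- neuron_model(kind, tau = 0.01, R = 1)
    cfg <- sim_config(settle = 0.005, init_seed = 3,
                      record_neurons = "all", map_neurons = integer(0),
                      n_pixels = 1)
    sim <- simulate_can(s$net, s$asg, traj, model, cfg)
    # replay in R
    S <- gridcan:::with_seed(3, runif(16))
    v <- velocity_series(traj)
    if (kind == "phenomenological") state <- list(u = S, S = S)
    if (kind == "mechanistic") m <- m_inf(S, model$S_half, model$k)
    stepR <- function(vv) {
      B <- feedforward_drive(s$prefs, s$asg$alpha_i, vv)
      if (kind == "integrator") {
        S <<- step_integrator(S, s$asg$W, B, s$asg$tau_i, 0.001)
      } else if (kind == "phenomenological") {
        r <- step_phenomenological(state, s$asg$W, B, s$asg$tau_i,
                                   model$epsilon, model$R, 0.001)
        state <<- r$state; S <<- r$S_out
      } else {
        r <- step_mechanistic(S, m, s$asg$W, B, s$asg$tau_i, model$g,
                              model$k, model$S_half, model$tau_m, 0.001)
        S <<- r$S; m <<- r$m
      }
    }
    for (t in 1:5) stepR(c(0, 0))          # settle
    expect_equal(as.vector(sim$S_settled), S, tolerance = 1e-5)
    ref <- matrix(NA_real_, nrow(v), 16)
    ref[1, ] <- S
    for (t in 2:nrow(v)) { stepR(v[t, ]); ref[t, ] <- S }
    expect_equal(sim$trace[[1]], ref, tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})

test_that("reduction chain is exact on identical seeds", {
  s <- tiny_setup(n = 6)
  traj <- straight_traj(50, v = c(0.001, 0.002))
  cfg <- sim_config(settle = 0.02, init_seed = c(5, 6),
                    record_neurons = "all", map_neurons = integer(0),
                    n_pixels = 1)
  base <- simulate_can(s$net, s$asg, traj,
                       neuron_model("integrator", tau = 0.01), cfg)
  phen0 <- simulate_can(s$net, s$asg, traj,
                        neuron_model("phenomenological", tau = 0.01,
                                     epsilon = 0, R = 1), cfg)
  mech0 <- simulate_can(s$net, s$asg, traj,
                        neuron_model("mechanistic", tau = 0.01, g = 0), cfg)
  for (k in 1:2) {
    expect_identical(base$trace[[k]], phen0$trace[[k]])
    expect_identical(base$trace[[k]], mech0$trace[[k]])
  }
  # determinism: identical config twice
  again <- simulate_can(s$net, s$asg, traj,
                        neuron_model("integrator", tau = 0.01), cfg)
  expect_identical(base$trace, again$trace)
})

test_that("integrator activity stays non-negative and below the drive bound", {
  s <- tiny_setup(n = 8)
  traj <- straight_traj(300, v = c(0.002, 0.001))
  cfg <- sim_config(settle = 0.05, init_seed = 2, record_neurons = "all",
                    map_neurons = integer(0), n_pixels = 1)
  sim <- simulate_can(s$net, s$asg, traj,
                      neuron_model("integrator", tau = 0.01), cfg)
  tr <- sim$trace[[1]]
  expect_gte(min(tr), 0)
  # all-inhibitory recurrence: S can never exceed the largest feed-forward
  # drive seen during the run (nor the initial condition's maximum)
  v <- velocity_series(traj)
  Bmax <- max(1 + 45 * abs(v))
  expect_lte(max(tr), max(Bmax, 1) + 1e-6)
})

test_that("unstable or divergent settings are caught", {
  s <- tiny_setup()
  traj <- straight_traj(10)
  bad <- s$asg
  bad$tau_i <- rep(0.0005, 16)   # dt > tau
  cfg <- sim_config(init_seed = 1, map_neurons = integer(0), n_pixels = 1)
  expect_error(simulate_can(s$net, bad, traj,
                            neuron_model("integrator"), cfg), "stability")
  warn <- s$asg
  warn$tau_i <- rep(0.0015, 16)  # dt/tau = 0.67
  expect_warning(simulate_can(s$net, warn, traj,
                              neuron_model("integrator"), cfg), "coarse")
  runaway <- s$asg
  runaway$W <- matrix(1, 16, 16)  # strongly excitatory
  expect_error(suppressWarnings(simulate_can(
    s$net, runaway, straight_traj(3000), neuron_model("integrator"),
    cfg)), "diverged")
})

test_that("settled homogeneous sheet forms a multi-bump pattern", {
  # period of the weight kernel's preferred mode is ~1.26 * lambda; on a
  # 48-lattice that admits roughly (48 / 16.4)^2 / sin(60 deg) bumps
  net <- can_network(n = 48)
  asg <- apply_heterogeneities(net, build_weight_matrix(net),
                               het_spec(degree = 0))
  traj <- straight_traj(2)
  cfg <- sim_config(settle = 1, init_seed = 1, record_neurons = 1:4,
                    map_neurons = integer(0), n_pixels = 1)
  sim <- simulate_can(net, asg, traj, neuron_model("integrator"), cfg)
  S <- matrix(sim$S_settled[, 1], 48, 48)
  nb <- function(M, dx, dy) M[(seq_len(48) + dx - 1) %% 48 + 1,
                              (seq_len(48) + dy - 1) %% 48 + 1]
  ismax <- matrix(TRUE, 48, 48)
  for (dx in -1:1) for (dy in -1:1) if (dx || dy) {
    ismax <- ismax & (S >= nb(S, dx, dy))
  }
  n_bumps <- sum(ismax & S > 0.2 * max(S))
  expect_gte(n_bumps, 5)
  expect_lte(n_bumps, 16)
  # the first recorded row is the settled state itself
  expect_lt(max(abs(sim$trace[[1]][1, ] - sim$S_settled[1:4, 1])), 1e-6)
})
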