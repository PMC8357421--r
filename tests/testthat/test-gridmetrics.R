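test_that("rate maps normalise activity by per-pixel visits", {
  traj <- generate_virtual_trajectory(can_arena(), duration = 0.5, seed = 4)
  act <- rep(2.5, length(traj$x))
  m <- compute_rate_map(act, traj = traj, n_pixels = 20)
  expect_equal(unique(m$values[m$valid]), 2.5)
  expect_equal(sum(m$occupancy), 1)
  # hand-built 3-sample check: two visits in one pixel, one in another
  tr3 <- traj
  tr3$x <- c(0.05, 0.06, 1.50)
  tr3$y <- c(0.05, 0.06, 1.50)
  m3 <- compute_rate_map(c(1, 3, 5), traj = tr3, n_pixels = 2)
  expect_equal(m3$values[1, 1], 2)     # (1+3)/2
  expect_equal(m3$values[2, 2], 5)
  expect_equal(sum(m3$valid), 2)
  expect_equal(m3$occupancy[1, 1], 2 / 3)
})

test_that("field detection recovers planted bumps and the 20% extent rule", {
  M <- synthetic_lattice_map(40, "hex", spacing = 14, sigma = 2,
                             phase = c(3, 2))
  map <- as_rate_map(M)
  fl <- detect_fields(map)
  # planted bump count within the arena (peaks separated by > 4 sigma)
  expect_gte(nrow(fl$peaks), 6)
  expect_lte(nrow(fl$peaks), 12)
  # each field contains its own peak and fields are disjoint
  for (f in seq_along(fl$fields)) {
    pk <- (fl$peaks$py[f] - 1) * 40 + fl$peaks$px[f]
    expect_true(pk %in% fl$fields[[f]])
  }
  expect_equal(anyDuplicated(unlist(fl$fields)), 0)
  # a single isolated bump: area matches the 20% contour disc 2 pi s^2 ln 5
  one <- matrix(0, 50, 50)
  px <- rep(seq_len(50) - 0.5, 50); py <- rep(seq_len(50) - 0.5, each = 50)
  sig <- 4
  one <- matrix(exp(-((px - 25)^2 + (py - 25)^2) / (2 * sig^2)), 50, 50)
  m1 <- as_rate_map(one, sigma_px = 0.5)
  f1 <- detect_fields(m1)
  expect_equal(nrow(f1$peaks), 1)
  expect_equal(f1$areas[1], 2 * pi * sig^2 * log(5), tolerance = 0.1)
  # two distant bumps -> two fields
  two <- one + matrix(exp(-((px - 8)^2 + (py - 8)^2) / 4), 50, 50)
  f2 <- detect_fields(as_rate_map(two, sigma_px = 0.5))
  expect_equal(nrow(f2$peaks), 2)
})

test_that("grid score separates hexagonal from square symmetry", {
  set.seed(42)
  for (i in 1:4) {
    ph <- runif(2, -6, 6); ang <- runif(1, 0, pi / 3)
    hexm <- synthetic_lattice_map(40, "hex", 12, 2.5, ph, ang)
    sqm <- synthetic_lattice_map(40, "square", 12, 2.5, ph, ang)
    expect_gt(grid_score(as_rate_map(hexm)), 0.5)
    expect_lte(grid_score(as_rate_map(sqm)), 0)
  }
  flat <- as_rate_map(matrix(1, 30, 30))
  expect_equal(grid_score(flat), 0)   # degenerate convention
})

test_that("grid score equals the brute-force oracle on random maps", {
  set.seed(11)
  np <- 20
  for (i in 1:6) {
    M <- synthetic_lattice_map(np, sample(c("hex", "square"), 1),
                               spacing = runif(1, 6, 9),
                               sigma = runif(1, 1.2, 2),
                               phase = runif(2, -3, 3),
                               angle = runif(1, 0, pi / 3)) +
      matrix(runif(np^2, 0, 0.1), np)
    valid <- matrix(TRUE, np, np)
    pipeline <- gridcan:::grid_score_batch(matrix(as.vector(M), ncol = 1),
                                           as.vector(valid), np)$score
    oracle <- grid_score_bruteforce(M, valid)
    expect_equal(pipeline, oracle, tolerance = 1e-6)
  }
})

test_that("autocorrelogram sanity: unit zero-lag and bounded values", {
  M <- synthetic_lattice_map(24, "hex", 8, 1.5, c(1, -2), 0.2)
  ac <- gridcan:::sac_batch(matrix(as.vector(M), ncol = 1),
                            rep(TRUE, 24^2), 24)
  A <- matrix(ac$sac[, 1], ac$side, ac$side)
  expect_equal(A[24, 24], 1, tolerance = 1e-9)
  expect_lte(max(A, na.rm = TRUE), 1 + 1e-9)
  expect_gte(min(A, na.rm = TRUE), -1 - 1e-9)
  # matches the direct-loop autocorrelogram
  Ab <- sac_bruteforce(M, matrix(TRUE, 24, 24))
  expect_equal(A, Ab, tolerance = 1e-9)
})

test_that("information rate and sparsity obey their closed forms", {
  # uniform map: zero information, unit sparsity
  uni <- as_rate_map(matrix(3, 20, 20))
  expect_equal(information_rate(uni), 0)
  expect_equal(sparsity(uni), 1)
  # single active pixel among N with uniform occupancy
  N <- 400; r <- 7
  single <- matrix(0, 20, 20); single[4, 9] <- r
  ms <- as_rate_map(single)
  expect_equal(information_rate(ms), (r / N) * log2(N))
  expect_equal(sparsity(ms), 1 / N)
  # doubling rates doubles information, leaves sparsity and score unchanged
  M <- synthetic_lattice_map(20, "hex", 7, 1.5, c(1, 1))
  m1 <- as_rate_map(M); m2 <- as_rate_map(2 * M)
  expect_equal(information_rate(m2), 2 * information_rate(m1))
  expect_equal(sparsity(m2), sparsity(m1))
  expect_equal(grid_score(m2), grid_score(m1), tolerance = 1e-9)
  expect_lte(sparsity(m1), 1)
})

test_that("metric summary assembles spacing, sizes and rates", {
  M <- matrix(0, 30, 30)
  px <- rep(seq_len(30) - 0.5, 30); py <- rep(seq_len(30) - 0.5, each = 30)
  add <- function(cx, cy) matrix(exp(-((px - cx)^2 + (py - cy)^2) / 6),
                                 30, 30)
  # bump centres on pixel centres so the detected peaks are exact
  M <- add(7.5, 14.5) + add(21.5, 14.5)
  sm <- summarize_metrics(as_rate_map(M, sigma_px = 0.5))
  expect_equal(sm$n_fields, 2)
  expect_equal(sm$avg_spacing_px, 14, tolerance = 0.01)
  # peak rate is read off the smoothed map
  expect_lte(sm$peak_rate, max(M))
  expect_gt(sm$peak_rate, 0.85 * max(M))
  # three collinear equidistant peaks: all-pairs mean = 4d/3
  M3 <- add(4.5, 14.5) + add(14.5, 14.5) + add(24.5, 14.5)
  sm3 <- summarize_metrics(as_rate_map(M3, sigma_px = 0.5))
  expect_equal(sm3$avg_spacing_px, 40 / 3, tolerance = 0.01)
  sm3n <- summarize_metrics(as_rate_map(M3, sigma_px = 0.5),
                            spacing_mode = "nearest_neighbor")
  expect_equal(sm3n$avg_spacing_px, 10, tolerance = 0.01)
})

test_that("percent change handles references and vectorisation", {
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(0, 4), -100)
  expect_equal(percent_change(-1, -2), 50)  # less negative = improvement
  expect_true(is.na(percent_change(3, 0)))
  set.seed(2)
  het <- rnorm(100); hom <- rnorm(100); hom[c(4, 40)] <- 0
  vec <- percent_change(het, hom)
  for (i in seq_along(het)) {
    ref <- if (hom[i] == 0) NA_real_ else 100 * (het[i] - hom[i]) / abs(hom[i])
    expect_equal(vec[i], ref)
  }
  expect_error(percent_change(1:3, 1:2), "equal length")
})

test_that("diagonal phase profile traces closed orbits for periodic maps", {
  # constant map: derivative identically zero
  flat <- as_rate_map(matrix(2, 25, 25))
  pp <- diagonal_phase_profile(flat)
  expect_equal(nrow(pp), 25)
  expect_equal(pp$derivative, rep(0, 25))
  # sinusoidal diagonal: elliptical orbit, derivative extremes at the
  # activity zero-crossings of the centred profile
  n <- 60
  M <- outer(seq_len(n), seq_len(n),
             function(i, j) 2 + sin(2 * pi * (i + j) / 24))
  pp2 <- diagonal_phase_profile(as_rate_map(M, sigma_px = 0.5))
  a <- pp2$activity - mean(pp2$activity)
  d <- pp2$derivative
  core <- 5:(n - 5)
  # orbit closes: (a / A)^2 + (d / D)^2 ~ 1
  A <- max(abs(a[core])); D <- max(abs(d[core]))
  radius <- (a[core] / A)^2 + (d[core] / D)^2
  expect_lt(max(abs(radius - 1)), 0.1)
})
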