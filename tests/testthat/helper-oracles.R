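# Independent oracles used across the test files. These deliberately avoid
# the package's vectorised/FFT code paths: plain loops and closed forms.

# Analytic optimum of the phenomenological resonator's chirp envelope:
# response magnitude ~ w^eps * (1 + w^2 tau^2)^(-(1+eps)/2), maximal at
# w*tau = sqrt(eps).
fr_analytic <- function(tau, epsilon) sqrt(epsilon) / (2 * pi * tau)

# Brute-force masked spatial autocorrelogram (direct lag loops).
sac_bruteforce <- function(M, valid, min_overlap = 20) {
  np <- nrow(M)
  side <- 2L * np - 1L
  out <- matrix(NA_real_, side, side)
  for (du in -(np - 1):(np - 1)) {
    for (dv in -(np - 1):(np - 1)) {
      xs <- c(); ys <- c()
      for (i in seq_len(np)) {
        for (j in seq_len(np)) {
          i2 <- i + du; j2 <- j + dv
          if (i2 < 1 || i2 > np || j2 < 1 || j2 > np) next
          if (!valid[i, j] || !valid[i2, j2]) next
          xs <- c(xs, M[i, j]); ys <- c(ys, M[i2, j2])
        }
      }
      if (length(xs) >= min_overlap && sd(xs) > 0 && sd(ys) > 0) {
        out[du + np, dv + np] <- cor(xs, ys)
      }
    }
  }
  out
}

# Brute-force grid score: autocorrelogram by direct loops, rotation by an
# independently written bilinear resampler, Pearson by cor().
grid_score_bruteforce <- function(M, valid, rotations = c(30, 60, 90, 120,
                                                          150)) {
  A <- sac_bruteforce(M, valid)
  side <- nrow(A)
  ctr <- side / 2
  ok <- !is.na(A)
  A0 <- ifelse(ok, A, 0)
  corr_at <- function(phi_deg) {
    phi <- phi_deg * pi / 180
    xs <- c(); ys <- c()
    for (i in seq_len(side)) {
      for (j in seq_len(side)) {
        if (!ok[i, j]) next
        # source coordinate of this target pixel under rotation by phi
        dx <- (i - 0.5) - ctr
        dy <- (j - 0.5) - ctr
        sx <- ctr + cos(phi) * dx + sin(phi) * dy
        sy <- ctr - sin(phi) * dx + cos(phi) * dy
        u <- sx - 0.5; v <- sy - 0.5
        i0 <- floor(u); j0 <- floor(v)
        if (i0 < 0 || i0 + 1 >= side || j0 < 0 || j0 + 1 >= side) next
        if (!ok[i0 + 1, j0 + 1] || !ok[i0 + 2, j0 + 1] ||
            !ok[i0 + 1, j0 + 2] || !ok[i0 + 2, j0 + 2]) next
        wx <- u - i0; wy <- v - j0
        val <- (1 - wx) * (1 - wy) * A0[i0 + 1, j0 + 1] +
          wx * (1 - wy) * A0[i0 + 2, j0 + 1] +
          (1 - wx) * wy * A0[i0 + 1, j0 + 2] +
          wx * wy * A0[i0 + 2, j0 + 2]
        xs <- c(xs, A0[i, j]); ys <- c(ys, val)
      }
    }
    cor(xs, ys)
  }
  r <- vapply(rotations, corr_at, numeric(1))
  names(r) <- paste0("r", rotations)
  min(r["r60"], r["r120"]) - max(r["r30"], r["r90"], r["r150"])
}

# Synthetic lattice rate maps (hexagonal or square) with Gaussian bumps.
synthetic_lattice_map <- function(n_pixels = 40, type = c("hex", "square"),
                                  spacing = 12, sigma = 2.5,
                                  phase = c(0, 0), angle = 0, peak = 1) {
  type <- match.arg(type)
  a1 <- spacing * c(cos(angle), sin(angle))
  th2 <- angle + if (type == "hex") pi / 3 else pi / 2
  a2 <- spacing * c(cos(th2), sin(th2))
  px <- rep(seq_len(n_pixels) - 0.5, n_pixels)
  py <- rep(seq_len(n_pixels) - 0.5, each = n_pixels)
  M <- matrix(0, n_pixels, n_pixels)
  ctr <- n_pixels / 2
  rng <- ceiling(2 * n_pixels / spacing) + 2
  for (i in -rng:rng) {
    for (j in -rng:rng) {
      cx <- ctr + phase[1] + i * a1[1] + j * a2[1]
      cy <- ctr + phase[2] + i * a1[2] + j * a2[2]
      if (cx < -4 * sigma || cx > n_pixels + 4 * sigma ||
          cy < -4 * sigma || cy > n_pixels + 4 * sigma) next
      M <- M + peak * matrix(exp(-((px - cx)^2 + (py - cy)^2) /
                                   (2 * sigma^2)), n_pixels, n_pixels)
    }
  }
  M
}

# Wrap a plain matrix into a can_rate_map with uniform occupancy. The
# default circle arena keeps every pixel valid and avoids the square-arena
# inscribed-circle mask, so oracles see exactly the given matrix.
as_rate_map <- function(M, arena = can_arena("circle", 2), sigma_px = 2) {
  np <- nrow(M)
  counts <- rep(1L, np * np)
  gridcan:::rate_map_from_counts(as.vector(M), counts, arena, np, sigma_px)
}
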