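# Grid-cell metrics: rotational grid score, information rate, sparsity,
# field statistics and phase-plane diagnostics.

# Bilinear resampling geometry for rotating an n x n pixel map about its
# centre. Returns, for each target pixel, the four source-pixel indices and
# weights; NA indices mark samples falling outside the grid.
rotation_geometry <- function(n_pixels, angle_deg) {
  key <- sprintf("rotgeom_%d_%g", n_pixels, angle_deg)
  cache_get_or(key, {
    n <- n_pixels
    phi <- angle_deg * pi / 180
    ctr <- n / 2
    px <- rep(seq_len(n) - 0.5, n)          # target pixel centres
    py <- rep(seq_len(n) - 0.5, each = n)
    # source = centre + Rot(-phi) (target - centre)
    dx <- px - ctr
    dy <- py - ctr
    sx <- ctr + cos(phi) * dx + sin(phi) * dy
    sy <- ctr - sin(phi) * dx + cos(phi) * dy
    ux <- sx - 0.5
    uy <- sy - 0.5
    i0 <- floor(ux)
    j0 <- floor(uy)
    wx <- ux - i0
    wy <- uy - j0
    idx <- cbind((j0) * n + i0 + 1, (j0) * n + i0 + 2,
                 (j0 + 1) * n + i0 + 1, (j0 + 1) * n + i0 + 2)
    ok <- i0 >= 0 & i0 + 1 < n & j0 >= 0 & j0 + 1 < n
    idx[!ok, ] <- NA_integer_
    wt <- cbind((1 - wx) * (1 - wy), wx * (1 - wy),
                (1 - wx) * wy, wx * wy)
    list(idx = idx, wt = wt, ok = ok)
  })
}

# Inscribed-circle mask (logical vector) for square arenas so every
# rotation angle compares identical support.
inscribed_circle_mask <- function(n_pixels) {
  key <- sprintf("circmask_%d", n_pixels)
  cache_get_or(key, {
    ctr <- n_pixels / 2
    px <- rep(seq_len(n_pixels) - 0.5, n_pixels)
    py <- rep(seq_len(n_pixels) - 0.5, each = n_pixels)
    (px - ctr)^2 + (py - ctr)^2 <= ctr^2
  })
}

# Masked spatial autocorrelograms of maps stored as columns of M
# (n_pixels^2 x K), sharing one validity mask. For each lag the Pearson
# correlation between the map and its shifted copy is computed over the
# overlapping valid pixels (FFT-accelerated sufficient statistics). Lags
# with fewer than min_overlap overlapping pixels are invalid. Returns the
# (2 n_pixels - 1)^2 x K matrix of correlations (centre row = zero lag) and
# the shared lag validity.
sac_batch <- function(M, valid, n_pixels, min_overlap = 20) {
  np <- n_pixels
  L <- stats::nextn(2 * np - 1, c(2, 3, 5))
  pad <- function(v) {
    P <- matrix(0, L, L)
    P[seq_len(np), seq_len(np)] <- matrix(v, np, np)
    P
  }
  # cross-correlation of A with B at all lags: iFFT(conj(F_A) * F_B)
  xc <- function(FA, FB) Re(fft(Conj(FA) * FB, inverse = TRUE)) / L^2
  # reorder wrapped lags into a (2np-1)^2 grid centred on zero lag
  ord <- c(L - ((np - 1):1) + 1L, 1L:np)
  m <- valid * 1
  Fm <- fft(pad(m))
  n_ov <- round(xc(Fm, Fm))[ord, ord]
  ok <- n_ov >= min_overlap
  K <- ncol(M)
  out <- matrix(NA_real_, (2 * np - 1)^2, K)
  for (j in seq_len(K)) {
    x <- M[, j] * m
    FX <- fft(pad(x))
    FX2 <- fft(pad(x^2))
    Sx <- xc(FX, Fm)[ord, ord]
    Sy <- xc(Fm, FX)[ord, ord]
    Sxx <- xc(FX2, Fm)[ord, ord]
    Syy <- xc(Fm, FX2)[ord, ord]
    Sxy <- xc(FX, FX)[ord, ord]
    num <- n_ov * Sxy - Sx * Sy
    den <- sqrt(pmax(n_ov * Sxx - Sx^2, 0) * pmax(n_ov * Syy - Sy^2, 0))
    r <- ifelse(ok & den > 1e-12 * pmax(n_ov, 1), num / den, NA_real_)
    out[, j] <- as.vector(r)
  }
  list(sac = out, ok = as.vector(ok), side = 2L * np - 1L)
}

# Rotation-correlation grid scores for maps stored as columns of M
# (n_pixels^2 x K), sharing one validity mask. The smoothed maps are turned
# into spatial autocorrelograms, which are rotated about the zero-lag
# centre; score = min(r60, r120) - max(r30, r90, r150).
grid_score_batch <- function(M, valid, n_pixels,
                             rotations = c(30, 60, 90, 120, 150),
                             circular_mask = FALSE) {
  M <- as.matrix(M)
  valid <- as.vector(valid)
  if (circular_mask) valid <- valid & inscribed_circle_mask(n_pixels)
  M0 <- M
  M0[!valid, ] <- 0
  ac <- sac_batch(M0, valid, n_pixels)
  side <- ac$side
  A <- ac$sac
  okA <- ac$ok & rowSums(is.na(A)) == 0
  A[is.na(A)] <- 0
  sac <- matrix(NA_real_, length(rotations), ncol(M))
  for (a in seq_along(rotations)) {
    g <- rotation_geometry(side, rotations[a])
    rowok <- g$ok & okA
    idx <- g$idx
    for (kk in 1:4) rowok <- rowok & !is.na(idx[, kk]) & okA[ifelse(
      is.na(idx[, kk]), 1L, idx[, kk])]
    idx[is.na(idx)] <- 1L
    Y <- g$wt[, 1] * A[idx[, 1], , drop = FALSE] +
      g$wt[, 2] * A[idx[, 2], , drop = FALSE] +
      g$wt[, 3] * A[idx[, 3], , drop = FALSE] +
      g$wt[, 4] * A[idx[, 4], , drop = FALSE]
    sac[a, ] <- colwise_pearson(A[rowok, , drop = FALSE],
                                Y[rowok, , drop = FALSE])
  }
  rownames(sac) <- paste0("sac", rotations)
  score <- pmin(sac["sac60", ], sac["sac120", ]) -
    pmax(sac["sac30", ], sac["sac90", ], sac["sac150", ])
  score[!is.finite(score)] <- 0   # degenerate (zero-variance) maps
  list(sac = sac, score = unname(score), autocorrelogram = A,
       autocorrelogram_ok = okA, side = side)
}

#' Rotational-symmetry grid score of a rate map
#'
#' Computes the masked spatial autocorrelogram of the smoothed map (Pearson
#' correlation between the map and its shifted copy at every lag, over the
#' overlapping valid pixels), rotates the autocorrelogram about its zero-lag
#' centre by 30/60/90/120/150 degrees (bilinear interpolation, using only
#' lags valid in both), and returns
#' \code{min(r60, r120) - max(r30, r90, r150)} where \code{r_phi} is the
#' correlation between the autocorrelogram and its phi-rotated copy. The
#' autocorrelogram centring makes the score invariant to the spatial phase
#' of the grid. Square arenas are masked to the inscribed circle first so
#' all angles compare identical support. Degenerate maps with zero variance
#' score 0 by convention.
#'
#' @param map A \code{can_rate_map}.
#' @param rotations Rotation angles in degrees.
#' @param use \code{"smoothed"} (default) or \code{"raw"} map values.
#' @return Scalar grid score.
#' @export
grid_score <- function(map, rotations = c(30, 60, 90, 120, 150),
                       use = c("smoothed", "raw")) {
  stopifnot(inherits(map, "can_rate_map"))
  use <- match.arg(use)
  if (mean(map$valid) < 0.10) {
    stop("fewer than 10% of pixels are valid; map too sparse to score")
  }
  M <- if (use == "smoothed") map$smoothed else map$values
  res <- grid_score_batch(matrix(ifelse(is.na(M), 0, M), ncol = 1),
                          as.vector(map$valid), map$n_pixels, rotations,
                          circular_mask = map$arena$shape == "square")
  res$score[1]
}

#' Spatial information rate of a rate map
#'
#' Skaggs information in bits per second:
#' \code{I = sum_m p_m mu_m log2(mu_m / mu)} over valid pixels, with
#' \code{mu = sum_m p_m mu_m} and \code{0 log 0 = 0}.
#'
#' @param map A \code{can_rate_map}.
#' @return Information rate (bits/s) computed from the raw rate values.
#' @export
information_rate <- function(map) {
  stopifnot(inherits(map, "can_rate_map"))
  sel <- map$valid
  p <- map$occupancy[sel]
  mu_m <- map$values[sel]
  mu <- sum(p * mu_m)
  if (mu <= 0) return(0)
  nz <- mu_m > 0
  sum(p[nz] * mu_m[nz] * log2(mu_m[nz] / mu))
}

#' Spatial sparsity of a rate map
#'
#' Ratio of squared mean rate to mean squared rate,
#' \code{mu^2 / sum_m p_m mu_m^2}; 1 for spatially uniform firing,
#' approaching 0 for highly selective firing.
#'
#' @param map A \code{can_rate_map}.
#' @return Sparsity in (0, 1], or NA for an all-zero map.
#' @export
sparsity <- function(map) {
  stopifnot(inherits(map, "can_rate_map"))
  sel <- map$valid
  p <- map$occupancy[sel]
  mu_m <- map$values[sel]
  denom <- sum(p * mu_m^2)
  if (denom == 0) return(NA_real_)
  sum(p * mu_m)^2 / denom
}

#' Assemble the grid-cell metrics of one neuron
#'
#' @param map A \code{can_rate_map}.
#' @param fields A \code{\link{detect_fields}} result (computed if missing).
#' @param spacing_mode \code{"all_pairs"} (mean over all pairwise peak
#'   distances) or \code{"nearest_neighbor"}. The all-pairs reading inflates
#'   spacing when many fields are present; the nearest-neighbour mode is
#'   provided for that reason.
#' @return One-row data frame with \code{grid_score}, \code{avg_rate},
#'   \code{peak_rate}, \code{n_fields}, \code{mean_field_size_px},
#'   \code{avg_spacing_px}, \code{info_rate_bits_s} and \code{sparsity}.
#'   Spacing is NA with fewer than two fields; field size 0 with none.
#' @export
summarize_metrics <- function(map, fields = detect_fields(map),
                              spacing_mode = c("all_pairs",
                                               "nearest_neighbor")) {
  stopifnot(inherits(map, "can_rate_map"))
  spacing_mode <- match.arg(spacing_mode)
  nf <- nrow(fields$peaks)
  spacing <- NA_real_
  if (nf >= 2L) {
    d <- as.matrix(dist(fields$peaks[, c("px", "py")]))
    spacing <- if (spacing_mode == "all_pairs") {
      mean(d[upper.tri(d)])
    } else {
      diag(d) <- Inf
      mean(apply(d, 1, min))
    }
  }
  data.frame(
    grid_score = grid_score(map),
    avg_rate = mean(map$values[map$valid]),
    peak_rate = max(map$smoothed[map$valid]),
    n_fields = nf,
    mean_field_size_px = if (nf > 0) sum(fields$areas) / nf else 0,
    avg_spacing_px = spacing,
    info_rate_bits_s = information_rate(map),
    sparsity = sparsity(map))
}

#' Percent change of a metric relative to a homogeneous reference
#'
#' \code{100 * (het - homo) / |homo|}, vectorised; entries with a zero
#' reference are returned as NA (undefined) so they drop out of aggregates.
#'
#' @param metric_het Metric values from the heterogeneous network.
#' @param metric_homo Matched values from the homogeneous twin.
#' @return Numeric vector of percent changes.
#' @export
percent_change <- function(metric_het, metric_homo) {
  if (length(metric_het) != length(metric_homo)) {
    stop("metric vectors must have equal length")
  }
  out <- 100 * (metric_het - metric_homo) / abs(metric_homo)
  out[metric_homo == 0] <- NA_real_
  out
}

#' Phase-plane profile along the main diagonal of a rate map
#'
#' Samples the smoothed map along its main diagonal and pairs each sample
#' with its spatial derivative (central differences; one-sided at the ends).
#' Closed orbits in this (activity, derivative) plane indicate spatially
#' periodic grid firing along the diagonal.
#'
#' @param map A \code{can_rate_map}.
#' @return Data frame with columns \code{activity} and \code{derivative},
#'   one row per diagonal pixel.
#' @export
diagonal_phase_profile <- function(map) {
  stopifnot(inherits(map, "can_rate_map"))
  a <- diag(map$smoothed)
  n <- length(a)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (a[3:n] - a[1:(n - 2)]) / 2
  if (n >= 2) {
    d[1] <- a[2] - a[1]
    d[n] <- a[n] - a[n - 1]
  }
  data.frame(activity = a, derivative = d)
}
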