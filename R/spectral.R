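# Frequency-domain analysis of temporal activity: magnitude spectra,
# normalised heterogeneous-vs-homogeneous differences, across-neuron
# variance profiles and octave AUC shares.

#' Magnitude spectra of neural temporal activity
#'
#' Single-sided FFT magnitude of each neuron's activity trace. No taper is
#' applied and the DC bin is retained: the analyses built on these spectra
#' target the lowest octaves, which a window would redistribute.
#'
#' @param trace Numeric matrix, time points x neurons (one column per
#'   neuron), covering the full post-settling run.
#' @param dt Sampling interval in seconds.
#' @param f_max Optional truncation frequency in Hz (default: keep all bins
#'   up to Nyquist).
#' @param demean Subtract each neuron's mean before transforming.
#' @return An object of class \code{can_spectrum}: \code{freqs} (Hz,
#'   resolution 1/run length) and \code{magnitude} (frequency bins x
#'   neurons).
#' @export
activity_spectrum <- function(trace, dt, f_max = NULL, demean = FALSE) {
  trace <- as.matrix(trace)
  stopifnot(dt > 0)
  n <- nrow(trace)
  if (n * dt < 2) stop("trace must cover at least 2 seconds")
  if (demean) trace <- sweep(trace, 2L, colMeans(trace))
  nf <- floor(n / 2) + 1L
  mag <- Mod(mvfft(trace))[seq_len(nf), , drop = FALSE]
  freqs <- (seq_len(nf) - 1L) / (n * dt)
  if (!is.null(f_max)) {
    keep <- freqs <= f_max
    mag <- mag[keep, , drop = FALSE]
    freqs <- freqs[keep]
  }
  structure(list(freqs = freqs, magnitude = mag, n_time = n, dt = dt),
            class = "can_spectrum")
}

#' Normalised spectral difference between paired runs
#'
#' For each neuron, the difference between its heterogeneous-network and
#' homogeneous-network magnitude spectra, normalised by the sum of the two
#' spectra's maxima:
#' \code{delta(f) = (S_het(f) - S_homo(f)) / (max S_het + max S_homo)}.
#' The two runs must share the frequency axis and the neuron ordering, and
#' are only meaningful when simulated with identical initial conditions and
#' trajectory (as \code{\link{run_experiment}} enforces).
#'
#' @param spec_het,spec_homo \code{can_spectrum} objects from the
#'   heterogeneous network and its homogeneous twin.
#' @return An object of class \code{can_spectral_comparison}: \code{freqs}
#'   and \code{delta} (frequency bins x neurons, each entry in [-1, 1]).
#' @export
normalized_spectral_difference <- function(spec_het, spec_homo) {
  stopifnot(inherits(spec_het, "can_spectrum"),
            inherits(spec_homo, "can_spectrum"))
  if (!isTRUE(all.equal(spec_het$freqs, spec_homo$freqs)) ||
      ncol(spec_het$magnitude) != ncol(spec_homo$magnitude)) {
    stop("spectra must share frequency axis and neuron set")
  }
  denom <- apply(spec_het$magnitude, 2L, max) +
    apply(spec_homo$magnitude, 2L, max)
  delta <- sweep(spec_het$magnitude - spec_homo$magnitude, 2L, denom, "/")
  structure(list(freqs = spec_het$freqs, delta = delta),
            class = "can_spectral_comparison")
}

#' Across-neuron variance of the normalised spectral difference
#'
#' @param comparison A \code{\link{normalized_spectral_difference}} result.
#' @param normalized Divide the profile by its own maximum.
#' @return Numeric vector: variance of \code{delta(f)} across neurons at
#'   each frequency bin.
#' @export
variance_profile <- function(comparison, normalized = FALSE) {
  stopifnot(inherits(comparison, "can_spectral_comparison"))
  d <- comparison$delta
  if (ncol(d) < 2L) stop("variance needs at least 2 neurons")
  v <- rowSums((d - rowMeans(d))^2) / (ncol(d) - 1L)
  if (normalized && max(v) > 0) v <- v / max(v)
  v
}

#' Octave-band shares of the area under a spectral profile
#'
#' Trapezoidal area under the profile within each octave band, expressed as
#' a percentage of either the whole spectrum's area (\code{full_spectrum})
#' or the summed band areas (\code{bands_total}; shares then add to 100).
#'
#' @param profile Numeric profile (e.g. a variance profile or one neuron's
#'   magnitude spectrum), or a \code{can_spectrum} (its neuron-mean
#'   magnitude is used).
#' @param freqs Frequency axis in Hz (taken from a \code{can_spectrum}
#'   automatically).
#' @param bands List of c(lo, hi) band edges in Hz.
#' @param denominator \code{"full_spectrum"} or \code{"bands_total"}.
#' @return Named numeric vector of percentage shares, one per band.
#' @export
octave_auc <- function(profile, freqs = NULL,
                       bands = list(c(0, 2), c(2, 4), c(4, 8), c(8, 16)),
                       denominator = c("full_spectrum", "bands_total")) {
  denominator <- match.arg(denominator)
  if (inherits(profile, "can_spectrum")) {
    freqs <- profile$freqs
    profile <- rowMeans(profile$magnitude)
  }
  stopifnot(is.numeric(profile), is.numeric(freqs),
            length(profile) == length(freqs))
  top <- max(vapply(bands, max, numeric(1)))
  if (max(freqs) < top) {
    stop(sprintf("frequency axis must reach %g Hz", top))
  }
  band_area <- vapply(bands, function(b) {
    xs <- sort(unique(c(b, freqs[freqs > b[1] & freqs < b[2]])))
    ys <- approx(freqs, profile, xout = xs)$y
    trapz_int(xs, ys)
  }, numeric(1))
  denom <- if (denominator == "full_spectrum") {
    trapz_int(freqs, profile)
  } else {
    sum(band_area)
  }
  shares <- 100 * band_area / denom
  names(shares) <- vapply(bands, function(b) sprintf("%g-%g Hz", b[1], b[2]),
                          character(1))
  shares
}
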