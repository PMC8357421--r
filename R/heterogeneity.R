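#' Parameter bounds for the five degrees of heterogeneity
#'
#' Uniform-distribution bounds used when randomising the integration time
#' constant (intrinsic, ms), the velocity scaling factor (afferent) and the
#' raw synaptic jitter (per-synapse additive, in raw units that are rescaled
#' by \code{jitter_scale} before being added to W). Degree 0 denotes the
#' homogeneous network.
#'
#' @return A data frame with one row per degree 1..5.
#' @export
het_bounds <- function() {
  data.frame(degree = 1:5,
             tau_lo_ms = c(8, 6, 4, 2, 1),
             tau_hi_ms = c(12, 14, 16, 18, 20),
             alpha_lo = c(35, 25, 15, 5, 0),
             alpha_hi = c(55, 65, 75, 85, 100),
             jitter_lo = 0,
             jitter_hi = c(300, 600, 900, 1200, 1500))
}

#' Heterogeneity specification
#'
#' Describes which biological heterogeneities to inject and how strongly.
#' Per-neuron parameters are drawn i.i.d. from the uniform ranges in
#' \code{\link{het_bounds}}; synaptic jitter is drawn independently per
#' ordered synapse and added to the weight matrix after scaling by
#' \code{jitter_scale}.
#'
#' The raw jitter bounds are enormous relative to the weights themselves
#' (|W| <= ~0.036), so a dimensionless scale is applied. Jitter is centred
#' by default: a positive-mean offset on every synapse shifts each neuron's
#' recurrent input by an amount that grows with the network size, flipping
#' the net-inhibitory network into runaway excitation well before the
#' jitter itself perturbs the connectivity structure; see the package
#' vignette for the calibration of the default scale.
#'
#' @param kinds Subset of \code{c("intrinsic", "afferent", "synaptic")}, or
#'   \code{"all"}.
#' @param degree Integer 0..5; 0 returns defaults exactly.
#' @param jitter_scale Dimensionless multiplier applied to the raw jitter
#'   draws.
#' @param jitter_centered If \code{TRUE} (default), draw jitter from
#'   \code{U[-bound/2, bound/2]}; \code{FALSE} draws from \code{U[0, bound]}
#'   (literal positive additive jitter, only usable at very small scales).
#' @param seed Integer seed controlling all draws.
#' @return An object of class \code{can_het_spec}.
#' @export
het_spec <- function(kinds = "all", degree = 0, jitter_scale = 1e-5,
                     jitter_centered = TRUE, seed = 1) {
  if (identical(kinds, "all")) kinds <- c("intrinsic", "afferent", "synaptic")
  bad <- setdiff(kinds, c("intrinsic", "afferent", "synaptic"))
  if (length(bad)) stop("unknown heterogeneity kind: ", paste(bad, collapse = ", "))
  if (!is.numeric(degree) || length(degree) != 1L || degree %% 1 != 0 ||
      degree < 0 || degree > 5) {
    stop("degree must be an integer in 0..5")
  }
  if (degree > 0 && length(kinds) == 0L) stop("kinds must be non-empty")
  structure(list(kinds = kinds, degree = as.integer(degree),
                 jitter_scale = jitter_scale,
                 jitter_centered = jitter_centered, seed = seed),
            class = "can_het_spec")
}

# Intrinsic bounds generalised to a non-default base tau: span grows by 20%
# of the base value per degree on either side, floored at 1 ms. For the
# default 10 ms base this reproduces het_bounds() exactly.
tau_bounds_ms <- function(tau_base_s, degree) {
  base <- tau_base_s * 1000
  c(lo = max(base * (1 - 0.2 * degree), 1), hi = base * (1 + 0.2 * degree))
}

#' Sample a heterogeneity assignment for a network
#'
#' Draws per-neuron integration time constants and velocity gains and (for
#' synaptic heterogeneity) a jittered copy of the weight matrix, according to
#' the requested kinds and degree. Unrequested kinds keep their homogeneous
#' defaults; degree 0 returns the defaults exactly. Reproducible from
#' \code{het$seed}.
#'
#' @param spec A \code{\link{can_network}}.
#' @param W Weight matrix from \code{\link{build_weight_matrix}}.
#' @param het A \code{\link{het_spec}}.
#' @return An object of class \code{can_het_assignment}: list with
#'   \code{tau_i} (seconds), \code{alpha_i}, \code{W} (possibly jittered),
#'   and the generating specs.
#' @export
apply_heterogeneities <- function(spec, W, het = het_spec()) {
  stopifnot(inherits(spec, "can_network"), inherits(het, "can_het_spec"))
  N <- spec$n^2
  stopifnot(nrow(W) == N, ncol(W) == N)
  tau_i <- rep(spec$tau, N)
  alpha_i <- rep(spec$alpha, N)
  W_out <- W
  if (het$degree > 0) {
    b <- het_bounds()[het$degree, ]
    with_seed(het$seed, {
      if ("intrinsic" %in% het$kinds) {
        tb <- tau_bounds_ms(spec$tau, het$degree)
        tau_i <- runif(N, tb["lo"], tb["hi"]) / 1000
      }
      if ("afferent" %in% het$kinds) {
        sc <- spec$alpha / 45   # bounds are stated for the default gain
        alpha_i <- runif(N, b$alpha_lo * sc, b$alpha_hi * sc)
      }
      if ("synaptic" %in% het$kinds) {
        raw <- if (het$jitter_centered) {
          runif(N * N, -b$jitter_hi / 2, b$jitter_hi / 2)
        } else {
          runif(N * N, 0, b$jitter_hi)
        }
        W_out <- W + matrix(raw * het$jitter_scale, N, N)
      }
    })
  }
  structure(list(tau_i = tau_i, alpha_i = alpha_i, W = W_out,
                 het = het, network = spec),
            class = "can_het_assignment")
}

#' @export
print.can_het_assignment <- function(x, ...) {
  cat(sprintf("<can_het_assignment> degree %d [%s], %d neurons\n",
              x$het$degree, paste(x$het$kinds, collapse = ", "),
              length(x$tau_i)))
  invisible(x)
}
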