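# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Column-wise Pearson correlation between two matrices of equal shape.
# Columns with zero variance in either argument yield NA.
colwise_pearson <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(identical(dim(X), dim(Y)))
  n <- nrow(X)
  if (n < 2L) return(rep(NA_real_, ncol(X)))
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  sx <- sqrt(colSums(Xc^2))
  sy <- sqrt(colSums(Yc^2))
  r <- colSums(Xc * Yc) / (sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  r
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Trapezoidal integral of y over x.
trapz_int <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

# Package-level cache for geometry operators (rotation/smoothing matrices).
.gridcan_cache <- new.env(parent = emptyenv())

cache_get_or <- function(key, expr) {
  if (!exists(key, envir = .gridcan_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .gridcan_cache)
  }
  get(key, envir = .gridcan_cache, inherits = FALSE)
}
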