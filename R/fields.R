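#' Detect grid firing fields in a smoothed rate map
#'
#' Local maxima of the smoothed map (8-neighbourhood dominance; plateaus of
#' equal value are merged and represented by the member pixel closest to
#' their centroid) seed the fields. Each field is grown over 8-connected
#' valid pixels whose value is at least \code{rel_threshold} times the peak
#' height; pixels reachable from several peaks are assigned to the nearest
#' one. Maxima below \code{abs_peak_min} are discarded as noise.
#'
#' @param map A \code{can_rate_map}.
#' @param rel_threshold Relative threshold defining a field's extent
#'   (fraction of its peak height).
#' @param abs_peak_min Minimum peak height (activity units) for a maximum to
#'   count as a field.
#' @return An object of class \code{can_field_set}: \code{peaks} (data frame
#'   with pixel coordinates \code{px}, \code{py} and \code{height}),
#'   \code{fields} (list of pixel-index vectors) and \code{areas} (pixels per
#'   field).
#' @export
detect_fields <- function(map, rel_threshold = 0.2, abs_peak_min = 0.1) {
  stopifnot(inherits(map, "can_rate_map"))
  M <- map$smoothed
  n <- map$n_pixels
  V <- map$valid
  Mp <- M
  Mp[!V] <- -Inf

  # strict 8-neighbourhood dominance with plateau merging
  pad <- matrix(-Inf, n + 2, n + 2)
  pad[2:(n + 1), 2:(n + 1)] <- Mp
  is_max <- matrix(TRUE, n, n)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- pad[(2:(n + 1)) + dx, (2:(n + 1)) + dy]
    is_max <- is_max & (Mp >= nb)
  }
  is_max <- is_max & V & is.finite(Mp)
  cand <- which(is_max)
  if (length(cand) == 0L) {
    return(structure(list(peaks = data.frame(px = integer(0),
                                             py = integer(0),
                                             height = numeric(0)),
                          fields = list(), areas = numeric(0),
                          n_pixels = n), class = "can_field_set"))
  }

  # merge connected equal-value plateaus into single peaks
  px <- ((cand - 1L) %% n) + 1L
  py <- ((cand - 1L) %/% n) + 1L
  comp <- integer(length(cand))
  cid <- 0L
  lookup <- setNames(seq_along(cand), as.character(cand))
  for (s in seq_along(cand)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      for (dx in -1:1) for (dy in -1:1) {
        qx <- px[cur] + dx
        qy <- py[cur] + dy
        if (qx < 1 || qx > n || qy < 1 || qy > n) next
        qi <- (qy - 1L) * n + qx
        m <- lookup[as.character(qi)]
        if (!is.na(m) && comp[m] == 0L && Mp[qi] == Mp[cand[cur]]) {
          comp[m] <- cid
          queue <- c(queue, m)
        }
      }
    }
  }
  peaks <- do.call(rbind, lapply(seq_len(cid), function(id) {
    sel <- comp == id
    cx <- mean(px[sel]); cy <- mean(py[sel])
    j <- which(sel)[which.min((px[sel] - cx)^2 + (py[sel] - cy)^2)]
    data.frame(px = px[j], py = py[j], height = M[cand[j]])
  }))
  peaks <- peaks[peaks$height >= abs_peak_min, , drop = FALSE]
  if (nrow(peaks) == 0L) {
    return(structure(list(peaks = peaks, fields = list(),
                          areas = numeric(0), n_pixels = n),
                     class = "can_field_set"))
  }
  peaks <- peaks[order(-peaks$height), , drop = FALSE]
  rownames(peaks) <- NULL

  # region-grow each peak; remember every claim, then resolve contested
  # pixels by distance to the claiming peaks
  claims <- vector("list", nrow(peaks))
  for (f in seq_len(nrow(peaks))) {
    thr <- rel_threshold * peaks$height[f]
    seen <- logical(n * n)
    start <- (peaks$py[f] - 1L) * n + peaks$px[f]
    queue <- start
    seen[start] <- TRUE
    member <- integer(0)
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      member <- c(member, cur)
      cx <- ((cur - 1L) %% n) + 1L
      cy <- ((cur - 1L) %/% n) + 1L
      for (dx in -1:1) for (dy in -1:1) {
        qx <- cx + dx; qy <- cy + dy
        if (qx < 1 || qx > n || qy < 1 || qy > n) next
        qi <- (qy - 1L) * n + qx
        if (!seen[qi] && V[qi] && is.finite(M[qi]) && M[qi] >= thr) {
          seen[qi] <- TRUE
          queue <- c(queue, qi)
        }
      }
    }
    claims[[f]] <- member
  }
  owner <- integer(n * n)
  best_d2 <- rep(Inf, n * n)
  for (f in seq_len(nrow(peaks))) {
    m <- claims[[f]]
    mx <- ((m - 1L) %% n) + 1L
    my <- ((m - 1L) %/% n) + 1L
    d2 <- (mx - peaks$px[f])^2 + (my - peaks$py[f])^2
    take <- d2 < best_d2[m]
    owner[m[take]] <- f
    best_d2[m[take]] <- d2[take]
  }
  fields <- lapply(seq_len(nrow(peaks)), function(f) which(owner == f))
  structure(list(peaks = peaks, fields = fields,
                 areas = lengths(fields), n_pixels = n),
            class = "can_field_set")
}

#' @export
print.can_field_set <- function(x, ...) {
  cat(sprintf("<can_field_set> %d field(s), mean area %.1f px\n",
              nrow(x$peaks),
              if (length(x$areas)) mean(x$areas) else NA_real_))
  invisible(x)
}
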