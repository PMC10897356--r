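#' Pairwise geographic distance within a landscape window
#'
#' Euclidean distance in metres between population reference points
#' (projected coordinates).  Patch polygons are not required; when only
#' point locations are available the point-to-point distance stands in for
#' the edge-to-edge patch distance.
#'
#' @param attrs population attribute data.frame with `population_id`,
#'   `window_id`, `x`, `y`.
#' @param window window id; all populations must belong to it.
#' @return symmetric distance matrix (metres) with population ids as
#'   dimnames.
#' @export
pairwise_geo_distance <- function(attrs, window) {
  a <- attrs[attrs$window_id == window, , drop = FALSE]
  if (!nrow(a)) stop("no populations in window ", window)
  d <- as.matrix(stats::dist(cbind(a$x, a$y)))
  dimnames(d) <- list(a$population_id, a$population_id)
  d
}

#' Calibrate the connectivity distance scale 1/alpha
#'
#' For each landscape window, the mean over populations of the distance to
#' their nearest neighbour; 1/alpha is the mean of those window means.
#' Windows with a single population carry no nearest-neighbour information
#' and are skipped with a warning.
#'
#' @param attrs population attribute data.frame (`population_id`,
#'   `window_id`, `x`, `y`).
#' @return 1/alpha in metres.
#' @export
calibrate_alpha <- function(attrs) {
  window_means <- c()
  for (w in unique(attrs$window_id)) {
    a <- attrs[attrs$window_id == w, , drop = FALSE]
    if (nrow(a) < 2L) {
      warning("window ", w, " has a single population; skipped in alpha calibration")
      next
    }
    d <- as.matrix(stats::dist(cbind(a$x, a$y)))
    diag(d) <- Inf
    window_means <- c(window_means, mean(apply(d, 1L, min)))
  }
  if (!length(window_means)) stop("no window with >= 2 populations")
  out <- mean(window_means)
  if (out <= 0) stop("degenerate alpha: all populations collocated")
  out
}

#' Hanski incidence-function spatial connectivity
#'
#' \deqn{C_i = \sum_{j \ne i} A_j^b e^{-\alpha d_{ij}}}
#' with \eqn{A_j} the census size of population j, \eqn{d_{ij}} the pairwise
#' distance in metres, \eqn{1/\alpha} the species' dispersal distance scale
#' (metres) and b the size exponent (0.5 by default, the conventional
#' square-root damping of patch size).  Sums run within each landscape
#' window only; a window's single population gets C = 0 (empty sum).
#'
#' @param attrs population attribute data.frame with `population_id`,
#'   `window_id`, `size`, `x`, `y`.
#' @param one_over_alpha distance scale 1/alpha in metres (e.g. from
#'   [calibrate_alpha()]).
#' @param b size exponent (default 0.5).
#' @return named numeric vector of connectivity values keyed by
#'   population id.
#' @export
hanski_connectivity <- function(attrs, one_over_alpha, b = 0.5) {
  stopifnot(one_over_alpha > 0, b >= 0)
  if (any(attrs$size < 0)) stop("negative population size")
  alpha <- 1 / one_over_alpha
  out <- stats::setNames(numeric(nrow(attrs)), attrs$population_id)
  for (w in unique(attrs$window_id)) {
    a <- attrs[attrs$window_id == w, , drop = FALSE]
    if (nrow(a) == 1L) { out[a$population_id] <- 0; next }
    d <- as.matrix(stats::dist(cbind(a$x, a$y)))
    K <- exp(-alpha * d) * rep(a$size^b, each = nrow(a))
    diag(K) <- 0
    out[a$population_id] <- rowSums(matrix(K, nrow(a)))
  }
  out
}
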