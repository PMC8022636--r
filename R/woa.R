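#' Draw the per-iteration whale-move parameters
#'
#' The stochastic coefficients of the whale optimization moves: `a` decays
#' linearly from 2 to 0 over the run; per dimension, `A = 2 a r - a` and
#' `C = 2 r'` with r, r' uniform on [0, 1]; `l` is uniform on [-1, 1] (spiral
#' pitch position); `p` and `theta` are uniform on [0, 1] (branch draws).
#'
#' @param t 0-based iteration index, `0 <= t < max_it`.
#' @param max_it total iterations.
#' @param dim number of position dimensions (k * f).
#' @return list with `a`, `A`, `C`, `l`, `p`, `theta`.
#' @export
woa_params <- function(t, max_it, dim) {
  stopifnot(t >= 0, t < max_it)
  a <- 2 * (1 - t / max_it)
  list(a = a,
       A = 2 * a * stats::runif(dim) - a,
       C = 2 * stats::runif(dim),
       l = stats::runif(1L, -1, 1),
       p = stats::runif(1L),
       theta = stats::runif(1L))
}

#' Encircling move toward a guide position
#'
#' The shrinking-encircling update: per dimension, D = |C * guide - pos| and
#' the new position is guide - A * D. With A = 0 the whale lands on the
#' guide; |A| >= 1 turns the same formula into exploration around a random
#' peer.
#'
#' @param position,guide flattened k*f position vectors.
#' @param A,C per-dimension coefficient vectors from [woa_params()].
#' @return the new position vector.
#' @export
woa_encircle <- function(position, guide, A, C) {
  if (length(position) != length(guide)) stop("position vectors differ in length")
  D <- abs(C * guide - position)
  guide - A * D
}

#' Bubble-net spiral move around a guide position
#'
#' The logarithmic-spiral update mimicking humpback bubble-net feeding:
#' per dimension, D' = |guide - pos| and the new position is
#' D' * exp(b l) * cos(2 pi l) + guide.
#'
#' @param position,guide flattened position vectors.
#' @param l spiral position in [-1, 1].
#' @param b spiral shape constant (default 1).
#' @return the new position vector.
#' @export
woa_spiral <- function(position, guide, l, b = 1) {
  if (length(position) != length(guide)) stop("position vectors differ in length")
  D <- abs(guide - position)
  D * exp(b * l) * cos(2 * pi * l) + guide
}

#' Centroid-exchange crossover between two solutions
#'
#' Draws m uniform in 1..(k-1) and a random subset of m centroid slots; the
#' offspring is the first solution with those centroids replaced by the
#' second solution's centroids at the same slots. Objectives are unset.
#'
#' @param s1,s2 solutions (lists with a k x f `$centroids` matrix).
#' @return offspring solution with `objectives = NULL`.
#' @export
crossover_solutions <- function(s1, s2) {
  k <- nrow(s1$centroids)
  if (k < 2L) stop("crossover needs at least 2 centroids")
  if (!all(dim(s1$centroids) == dim(s2$centroids)))
    stop("solutions differ in shape")
  m <- sample.int(k - 1L, 1L)
  idx <- sample.int(k, m)
  cent <- s1$centroids
  cent[idx, ] <- s2$centroids[idx, , drop = FALSE]
  list(centroids = cent, objectives = NULL)
}
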