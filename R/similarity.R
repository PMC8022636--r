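#' Minimum-order ranks
#'
#' Ranks a vector with the minimum-order tie rule: every value receives
#' 1 + (number of strictly smaller values), so tied values share the smallest
#' rank among their positions. A strictly increasing row maps to 1..f.
#'
#' @param x numeric vector (length >= 2, all finite).
#' @return numeric vector of 1-based ranks.
#' @export
min_rank <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values to rank")
  if (any(!is.finite(x))) stop("non-finite value in rank input")
  rank(x, ties.method = "min")
}

#' Row-wise minimum-order rank matrix
#'
#' Transforms each gene's expression profile into its minimum-order ranks.
#' Used by the Spearman distance: centroids stay in raw expression space and
#' are rank-transformed on the fly, while the data are transformed once here.
#'
#' @param x expression matrix.
#' @return matrix of the same shape and dimnames holding per-row ranks.
#' @export
rank_matrix <- function(x) {
  x <- as.matrix(x)
  r <- t(apply(x, 1L, min_rank))
  dimnames(r) <- dimnames(x)
  r
}

#' Spearman coefficient from rank vectors
#'
#' Computes r_s = 1 - 6 * sum(d_i^2) / (n (n^2 - 1)) with d_i the per-position
#' rank differences. The classical closed form is used exactly as stated; it
#' is not tie-corrected, so with minimum-order ranks and ties the result can
#' fall slightly outside [-1, 1]. No clamping is applied.
#'
#' @param x_ranks,y_ranks rank vectors of equal length n >= 2.
#' @return the Spearman coefficient.
#' @export
spearman_coef <- function(x_ranks, y_ranks) {
  if (length(x_ranks) != length(y_ranks))
    stop("rank vectors differ in length")
  n <- length(x_ranks)
  if (n < 2L) stop("need at least 2 ranks")
  d <- x_ranks - y_ranks
  1 - 6 * sum(d * d) / (n * (n * n - 1))
}

#' Point-to-point distance under the run's metric
#'
#' The single distance used throughout a run — by the objectives, the
#' assignment step and the validation indices. `euclidean` is the L2 norm of
#' the difference; `spearman` is 1 - r_s computed on the minimum-order ranks
#' of the two vectors (range [0, 2], 0 at perfect rank agreement).
#'
#' @param a,b numeric vectors of equal length.
#' @param metric `"euclidean"` or `"spearman"`.
#' @return non-negative distance.
#' @export
profile_distance <- function(a, b, metric = c("euclidean", "spearman")) {
  metric <- match.arg(metric)
  if (length(a) != length(b)) stop("vectors differ in length")
  if (metric == "euclidean") {
    sqrt(sum((a - b)^2))
  } else {
    1 - spearman_coef(min_rank(a), min_rank(b))
  }
}

# All-pairs distances between the rows of X (n x f) and C (k x f) under the
# run metric, vectorised. Under spearman, Xr are the precomputed row ranks of
# X; centroid rows are ranked here. Returns an n x k matrix.
.distance_matrix <- function(X, C, metric, Xr = NULL) {
  if (metric == "euclidean") {
    cross <- X %*% t(C)
    d2 <- outer(rowSums(X * X), rep(1, nrow(C))) +
      outer(rep(1, nrow(X)), rowSums(C * C)) - 2 * cross
    d2[d2 < 0] <- 0
    sqrt(d2)
  } else {
    if (is.null(Xr)) Xr <- rank_matrix(X)
    Cr <- rank_matrix(C)
    f <- ncol(Xr)
    # sum d^2 between rank rows via the cross-product expansion
    s <- outer(rowSums(Xr * Xr), rep(1, nrow(Cr))) +
      outer(rep(1, nrow(Xr)), rowSums(Cr * Cr)) - 2 * Xr %*% t(Cr)
    rs <- 1 - 6 * s / (f * (f * f - 1))
    1 - rs
  }
}
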