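#' Nearest- and second-nearest-centroid assignment
#'
#' For each data point, finds the index of its nearest centroid (`i_min`,
#' ties broken toward the lowest index), the distance to it (`d1`) and the
#' distance to the nearest of the remaining centroids (`d2`). The
#' second-nearest distance is what the Simple Silhouette objective needs; it
#' is part of the per-partition payload of the parallel evaluation contract.
#'
#' @param data expression matrix (n x f).
#' @param centroids k x f matrix of centroids in raw expression space, k >= 2.
#' @param metric distance metric for the run.
#' @param data_ranks optional precomputed `rank_matrix(data)` (spearman only).
#' @param rows optional row indices restricting assignment to a partition.
#' @return list with integer `i_min` and numeric `d1`, `d2`, each indexed by
#'   (and named after) the data rows assigned.
#' @export
assign_points <- function(data, centroids, metric = c("euclidean", "spearman"),
                          data_ranks = NULL, rows = NULL) {
  metric <- match.arg(metric)
  data <- as.matrix(data)
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  if (k < 2L) stop("need at least 2 centroids (second-nearest distance undefined)")
  if (ncol(centroids) != ncol(data)) stop("feature counts differ")
  if (is.null(rows)) rows <- seq_len(nrow(data))
  X <- data[rows, , drop = FALSE]
  Xr <- if (!is.null(data_ranks)) data_ranks[rows, , drop = FALSE] else NULL
  D <- .distance_matrix(X, centroids, metric, Xr)
  i_min <- max.col(-D, ties.method = "first")
  idx <- cbind(seq_len(nrow(D)), i_min)
  d1 <- D[idx]
  D[idx] <- Inf
  i2 <- max.col(-D, ties.method = "first")
  d2 <- D[cbind(seq_len(nrow(D)), i2)]
  list(row = rows, i_min = i_min, d1 = d1, d2 = d2)
}

#' Xie-Beni index of an assignment
#'
#' Compactness-to-separation ratio: the summed squared distances of points to
#' their assigned centroid, divided by n times the minimum squared
#' centroid-to-centroid distance. Lower is better. Centroid-centroid
#' distances use the same metric as point assignment.
#'
#' @param assignment result of [assign_points()].
#' @param centroids the solution's centroids.
#' @param metric distance metric.
#' @param n total number of points.
#' @return non-negative Xie-Beni value.
#' @export
xie_beni <- function(assignment, centroids, metric = c("euclidean", "spearman"),
                     n = length(assignment$d1)) {
  metric <- match.arg(metric)
  centroids <- as.matrix(centroids)
  CD <- .distance_matrix(centroids, centroids, metric)
  diag(CD) <- Inf
  sep <- min(CD)^2
  if (sep == 0)
    stop("degenerate solution: coincident centroids (zero separation)")
  sum(assignment$d1^2) / (n * sep)
}

#' Overall cluster deviation of an assignment
#'
#' The summed distance of every point to its assigned centroid — a pure
#' compactness objective, minimized.
#'
#' @inheritParams xie_beni
#' @return non-negative deviation.
#' @export
overall_deviation <- function(assignment) {
  sum(assignment$d1)
}

#' Simple Silhouette Index of an assignment
#'
#' Centroid-based silhouette surrogate: ss(i) = 1 - a'/b' with a' the
#' distance to the point's own (nearest) centroid and b' the distance to the
#' nearest other centroid, averaged over points; maximized. Unlike the full
#' Silhouette it needs only the two smallest point-to-centroid distances, so
#' it parallelizes over data partitions. A point coincident with two
#' centroids (b' = 0) scores 0.
#'
#' @inheritParams xie_beni
#' @return value in [0, 1] for nearest-centroid assignments.
#' @export
simple_silhouette <- function(assignment) {
  a <- assignment$d1
  b <- assignment$d2
  ss <- ifelse(b == 0, 0, 1 - a / b)
  mean(ss)
}

#' Evaluate the three clustering objectives of a set of centroids
#'
#' The partition-parallel evaluation contract: data rows are split into
#' partitions; each partition independently computes its points'
#' (nearest index, nearest distance, second-nearest distance) triples; the
#' coordinator concatenates them by row index and computes Xie-Beni, overall
#' deviation and the Simple Silhouette. The result does not depend on the
#' partition count or boundaries (up to floating summation order).
#'
#' @param centroids k x f matrix (or a solution list holding `$centroids`).
#' @param data expression matrix.
#' @param metric distance metric.
#' @param partitions number of row partitions (contiguous chunks).
#' @param backend `"serial"` maps partitions in the coordinator process;
#'   `"process"` maps them over a process pool (`parallel::mclapply`).
#' @param data_ranks optional precomputed rank matrix (spearman).
#' @param cores process-pool width for the `"process"` backend.
#' @return named numeric vector `c(xb=, dev=, ssi=)`.
#' @export
evaluate_objectives <- function(centroids, data,
                                metric = c("euclidean", "spearman"),
                                partitions = 1L, backend = c("serial", "process"),
                                data_ranks = NULL, cores = 2L) {
  metric <- match.arg(metric)
  backend <- match.arg(backend)
  if (is.list(centroids) && !is.null(centroids$centroids))
    centroids <- centroids$centroids
  centroids <- as.matrix(centroids)
  data <- as.matrix(data)
  n <- nrow(data)
  if (metric == "spearman" && is.null(data_ranks)) data_ranks <- rank_matrix(data)
  partitions <- max(1L, min(as.integer(partitions), n))
  chunks <- parallel::splitIndices(n, partitions)
  map_fun <- function(rows)
    assign_points(data, centroids, metric, data_ranks = data_ranks, rows = rows)
  parts <- if (backend == "process" && .Platform$OS.type == "unix") {
    parallel::mclapply(chunks, map_fun, mc.cores = cores)
  } else {
    lapply(chunks, map_fun)
  }
  # reduce: concatenate keyed by row index, then reorder to input order
  row <- unlist(lapply(parts, `[[`, "row"), use.names = FALSE)
  ord <- order(row)
  asg <- list(row = row[ord],
              i_min = unlist(lapply(parts, `[[`, "i_min"), use.names = FALSE)[ord],
              d1 = unlist(lapply(parts, `[[`, "d1"), use.names = FALSE)[ord],
              d2 = unlist(lapply(parts, `[[`, "d2"), use.names = FALSE)[ord])
  c(xb = xie_beni(asg, centroids, metric, n = n),
    dev = overall_deviation(asg),
    ssi = simple_silhouette(asg))
}
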