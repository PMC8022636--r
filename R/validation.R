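# Full pairwise distance matrix under the run metric.
.pairwise_distances <- function(data, metric) {
  data <- as.matrix(data)
  if (metric == "euclidean") {
    as.matrix(stats::dist(data))
  } else {
    D <- .distance_matrix(data, data, metric)
    dimnames(D) <- NULL
    D
  }
}

#' Full Silhouette width of a labeled dataset
#'
#' The point-level cohesion/separation score: s(i) = (b_i - a_i) /
#' max(a_i, b_i) with a_i the mean distance of point i to the other members
#' of its own cluster and b_i the smallest, over the other clusters, of the
#' mean distance to that cluster's members. Points in singleton clusters
#' score 0. The index is the mean of s(i) over all n points; higher is
#' better, and the optimizer uses it to pick the final solution from the
#' Pareto front.
#'
#' @param data expression matrix, or a precomputed symmetric distance matrix
#'   when `is_dist = TRUE`.
#' @param labels integer cluster labels (1-based).
#' @param metric distance metric (ignored when `is_dist`).
#' @param is_dist whether `data` is already a pairwise distance matrix.
#' @return value in [-1, 1].
#' @export
silhouette_index <- function(data, labels, metric = c("euclidean", "spearman"),
                             is_dist = FALSE) {
  metric <- match.arg(metric)
  labels <- as.integer(labels)
  D <- if (is_dist) as.matrix(data) else .pairwise_distances(data, metric)
  n <- length(labels)
  if (nrow(D) != n) stop("labels must have one entry per point")
  present <- sort(unique(labels))
  if (length(present) < 2L) stop("silhouette needs at least 2 non-empty clusters")
  idx <- lapply(present, function(g) which(labels == g))
  sizes <- lengths(idx)
  s <- numeric(n)
  for (ci in seq_along(present)) {
    rows <- idx[[ci]]
    if (sizes[ci] == 1L) { s[rows] <- 0; next }
    # mean distance of each member to the rest of its cluster
    a <- rowSums(D[rows, rows, drop = FALSE]) / (sizes[ci] - 1L)
    b <- rep(Inf, length(rows))
    for (cj in seq_along(present)) {
      if (cj == ci) next
      bj <- rowSums(D[rows, idx[[cj]], drop = FALSE]) / sizes[cj]
      b <- pmin(b, bj)
    }
    s[rows] <- (b - a) / pmax(a, b)
    s[rows][a == 0 & b == 0] <- 0
  }
  mean(s)
}

#' Davies-Bouldin index
#'
#' For each cluster pair, the ratio of summed within-cluster scatters to the
#' centroid separation; the index averages each cluster's worst-case ratio.
#' Lower is better. By default the scatter S_k is the mean distance of
#' cluster k's points to the supplied centroid — the representation the
#' optimizer actually produced; set `recompute_centroids = TRUE` to use the
#' per-cluster feature means instead.
#'
#' @param data expression matrix.
#' @param labels integer cluster labels (1-based, matching centroid rows).
#' @param centroids k x f matrix; required unless `recompute_centroids`.
#' @param metric distance metric.
#' @param recompute_centroids replace centroids by cluster means.
#' @return non-negative index value.
#' @export
davies_bouldin <- function(data, labels, centroids = NULL,
                           metric = c("euclidean", "spearman"),
                           recompute_centroids = is.null(centroids)) {
  metric <- match.arg(metric)
  data <- as.matrix(data)
  labels <- as.integer(labels)
  present <- sort(unique(labels))
  if (length(present) < 2L) stop("Davies-Bouldin needs at least 2 clusters")
  if (recompute_centroids) {
    centroids <- do.call(rbind, lapply(present, function(g)
      colMeans(data[labels == g, , drop = FALSE])))
  } else {
    if (is.null(centroids)) stop("centroids required")
    centroids <- as.matrix(centroids)[present, , drop = FALSE]
  }
  m <- length(present)
  Dc <- .distance_matrix(data, centroids, metric)
  S <- vapply(seq_len(m), function(i)
    mean(Dc[labels == present[i], i]), numeric(1L))
  M <- .distance_matrix(centroids, centroids, metric)
  diag(M) <- Inf
  if (min(M) == 0) stop("degenerate clustering: coincident centroids")
  worst <- vapply(seq_len(m), function(i)
    max((S[i] + S[-i]) / M[i, -i]), numeric(1L))
  mean(worst)
}

#' Dunn index
#'
#' The smallest between-cluster separation divided by the largest cluster
#' diameter; higher is better. Separation is single linkage (the minimum
#' pairwise point distance between two clusters) and the diameter is the
#' maximum pairwise distance within a cluster.
#'
#' @inheritParams silhouette_index
#' @return non-negative index value.
#' @export
dunn_index <- function(data, labels, metric = c("euclidean", "spearman"),
                       is_dist = FALSE) {
  metric <- match.arg(metric)
  labels <- as.integer(labels)
  D <- if (is_dist) as.matrix(data) else .pairwise_distances(data, metric)
  present <- sort(unique(labels))
  if (length(present) < 2L) stop("Dunn index needs at least 2 clusters")
  idx <- lapply(present, function(g) which(labels == g))
  diam <- max(vapply(idx, function(r)
    if (length(r) < 2L) 0 else max(D[r, r]), numeric(1L)))
  if (diam == 0) stop("degenerate clustering: all clusters are singletons or points coincide")
  sep <- Inf
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    if (j <= i) next
    sep <- min(sep, min(D[idx[[i]], idx[[j]]]))
  }
  sep / diam
}

#' F-measure between a clustering and reference classes
#'
#' The information-retrieval F-measure of a partition against known classes:
#' for class i and cluster j, precision p = n_ij / n_j and recall
#' r = n_ij / n_i combine into F(i,j) = 2pr/(p+r); each class contributes
#' its best-matching cluster's F, weighted by class size. Invariant under
#' relabeling of the predicted cluster ids; 1 for a perfect recovery.
#'
#' @param labels_pred predicted cluster labels.
#' @param labels_true reference class labels.
#' @return value in [0, 1].
#' @export
f_measure <- function(labels_pred, labels_true) {
  if (length(labels_pred) != length(labels_true))
    stop("label vectors differ in length")
  tab <- table(true = labels_true, pred = labels_pred)
  n <- length(labels_true)
  n_i <- rowSums(tab)
  n_j <- colSums(tab)
  total <- 0
  for (i in seq_len(nrow(tab))) {
    best <- 0
    for (j in seq_len(ncol(tab))) {
      nij <- tab[i, j]
      if (nij == 0) next
      p <- nij / n_j[j]
      r <- nij / n_i[i]
      best <- max(best, 2 * p * r / (p + r))
    }
    total <- total + (n_i[i] / n) * best
  }
  unname(total)
}

#' Select the best solution from an elite list by full Silhouette
#'
#' Labels each elite member's nearest-centroid partition of the data and
#' computes its full Silhouette width; the member with the highest value is
#' returned (ties keep the earliest member). Members whose centroids leave
#' fewer than two non-empty clusters are skipped with a warning. The pairwise
#' distance matrix is computed once and shared across members.
#'
#' @param el elite list with evaluated solutions.
#' @param data expression matrix the list was built on.
#' @param metric distance metric of the run.
#' @param data_ranks optional precomputed rank matrix (spearman).
#' @param true_labels optional reference classes; adds F-measure to the
#'   report.
#' @return list with `solution`, `labels`, `silhouette` and a `report` list
#'   (silhouette, dbi, dunn, optionally f_measure).
#' @export
select_best_solution <- function(el, data, metric = c("euclidean", "spearman"),
                                 data_ranks = NULL, true_labels = NULL) {
  metric <- match.arg(metric)
  if (length(el$solutions) == 0L) stop("elite list is empty")
  data <- as.matrix(data)
  if (metric == "spearman" && is.null(data_ranks)) data_ranks <- rank_matrix(data)
  D <- .pairwise_distances(data, metric)
  best_i <- 0L
  best_s <- -Inf
  best_labels <- NULL
  for (i in seq_along(el$solutions)) {
    asg <- assign_points(data, el$solutions[[i]]$centroids, metric,
                         data_ranks = data_ranks)
    labels <- asg$i_min
    if (length(unique(labels)) < 2L) {
      warning(sprintf("elite member %d yields a single cluster; skipped", i))
      next
    }
    s <- silhouette_index(D, labels, is_dist = TRUE)
    if (s > best_s) {
      best_s <- s
      best_i <- i
      best_labels <- labels
    }
  }
  if (best_i == 0L) stop("no elite member yields a valid clustering")
  sol <- el$solutions[[best_i]]
  report <- list(silhouette = best_s,
                 dbi = davies_bouldin(data, best_labels, sol$centroids, metric),
                 dunn = dunn_index(D, best_labels, is_dist = TRUE))
  if (!is.null(true_labels))
    report$f_measure <- f_measure(best_labels, true_labels)
  list(solution = sol, labels = best_labels, silhouette = best_s,
       report = report)
}
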