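#' Pareto dominance over the three clustering objectives
#'
#' Solution u dominates v when it is no worse in all three objectives —
#' Xie-Beni and deviation minimized, Simple Silhouette maximized — and
#' strictly better in at least one. A vector never dominates itself.
#'
#' @param u,v named objective vectors with components `xb`, `dev`, `ssi`.
#' @return logical.
#' @export
dominates <- function(u, v) {
  if (any(!is.finite(u)) || any(!is.finite(v)))
    stop("objective vectors must be finite")
  no_worse <- u[["xb"]] <= v[["xb"]] && u[["dev"]] <= v[["dev"]] &&
    u[["ssi"]] >= v[["ssi"]]
  better <- u[["xb"]] < v[["xb"]] || u[["dev"]] < v[["dev"]] ||
    u[["ssi"]] > v[["ssi"]]
  no_worse && better
}

#' Crowding distance of a set of objective vectors
#'
#' The standard per-objective normalized gap sum used to decide which member
#' of a full archive to drop: for each objective the points are sorted, the
#' extremes get infinite distance, and interior points accumulate the gap
#' between their neighbours divided by the objective's range. Larger means
#' more isolated on the front; boundary points are never removed.
#'
#' @param points matrix with one row per solution and columns `xb`, `dev`,
#'   `ssi` (any orientation of each objective — the measure is symmetric).
#' @return numeric vector of crowding distances (may be `Inf`).
#' @export
crowding_distance <- function(points) {
  points <- rbind(points)
  m <- nrow(points)
  if (m == 0L) return(numeric(0))
  if (m <= 2L) return(rep(Inf, m))
  cd <- numeric(m)
  for (j in seq_len(ncol(points))) {
    o <- order(points[, j])
    rng <- points[o[m], j] - points[o[1L], j]
    cd[o[1L]] <- Inf
    cd[o[m]] <- Inf
    if (rng > 0) {
      gaps <- (points[o[3:m], j] - points[o[1:(m - 2L)], j]) / rng
      cd[o[2:(m - 1L)]] <- cd[o[2:(m - 1L)]] + gaps
    }
  }
  cd
}

#' Create an empty elite list
#'
#' The elite list is the tabu-search memory of the optimizer: a bounded
#' archive of mutually non-dominated solutions that guides every swarm move.
#'
#' @param capacity maximum number of stored solutions.
#' @return an object of class `elite_list`.
#' @export
elite_list <- function(capacity = 50L) {
  stopifnot(capacity >= 1L)
  structure(list(solutions = list(), capacity = as.integer(capacity)),
            class = "elite_list")
}

#' @export
length.elite_list <- function(x) length(x$solutions)

#' @export
print.elite_list <- function(x, ...) {
  cat(sprintf("Elite list: %d / %d non-dominated solutions\n",
              length(x$solutions), x$capacity))
  invisible(x)
}

#' Objective matrix of an elite list
#'
#' @param el elite list.
#' @return matrix with one row per member, columns `xb`, `dev`, `ssi`.
#' @export
el_objectives <- function(el) {
  if (length(el$solutions) == 0L)
    return(matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("xb", "dev", "ssi"))))
  do.call(rbind, lapply(el$solutions, function(s) s$objectives[c("xb", "dev", "ssi")]))
}

#' Offer a candidate solution to the elite list
#'
#' If any member dominates the candidate, or a member with an identical
#' objective vector is already present, the list is unchanged. Otherwise all
#' members the candidate dominates are removed and the candidate inserted;
#' if the list then exceeds its capacity, the member with the smallest
#' crowding distance is dropped (boundary members, with infinite crowding
#' distance, survive).
#'
#' @param el elite list.
#' @param solution list with `$centroids` (k x f matrix) and `$objectives`
#'   (named vector `xb`, `dev`, `ssi`).
#' @return list with the updated `el` and logical `changed` (whether
#'   membership changed).
#' @export
el_update <- function(el, solution) {
  if (is.null(solution$objectives) || anyNA(solution$objectives))
    stop("candidate has no evaluated objectives")
  obj <- solution$objectives[c("xb", "dev", "ssi")]
  M <- el_objectives(el)
  for (i in seq_len(nrow(M))) {
    if (all(M[i, ] == obj) || dominates(M[i, ], obj))
      return(list(el = el, changed = FALSE))
  }
  keep <- !vapply(seq_len(nrow(M)), function(i) dominates(obj, M[i, ]), logical(1L))
  el$solutions <- c(el$solutions[keep], list(solution))
  if (length(el$solutions) > el$capacity) {
    cd <- crowding_distance(el_objectives(el))
    el$solutions <- el$solutions[-which.min(cd)]
  }
  list(el = el, changed = TRUE)
}

#' Serialize an elite list to delimited text
#'
#' One row per solution: the flattened centroid matrix (row-major by
#' centroid) followed by the three objectives.
#'
#' @param el elite list.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_elite_list <- function(el, path) {
  rows <- lapply(el$solutions, function(s) {
    c(as.vector(t(s$centroids)), s$objectives[c("xb", "dev", "ssi")])
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- matrix(numeric(0), 0L, 0L)
  k <- if (length(el$solutions)) nrow(el$solutions[[1L]]$centroids) else 0L
  f <- if (k) ncol(el$solutions[[1L]]$centroids) else 0L
  cn <- c(if (k) paste0("c", rep(seq_len(k), each = f), "_f", rep(seq_len(f), k)),
          "xb", "dev", "ssi")
  if (ncol(tab)) colnames(tab) <- cn
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
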