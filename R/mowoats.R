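#' Control parameters for the MOWOATS optimizer
#'
#' Defaults follow the algorithm's published configuration: 50 iterations, a
#' swarm of 15 whales, an elite list of capacity 50, and a stagnation
#' threshold of 2 iterations without elite-list improvement before a
#' crossover phase fires. `p_threshold` splits each whale's move draw:
#' above it the whale encircles (an elite member when the move coefficients
#' are small, a random peer otherwise), at or below it the whale performs
#' the bubble-net move around an elite member.
#'
#' @param max_it iterations of the main loop.
#' @param np swarm (population) size.
#' @param max_el elite-list capacity.
#' @param max_non_improve consecutive non-improving iterations that trigger
#'   a crossover phase.
#' @param p_threshold branch probability split in (0, 1).
#' @param spiral_b spiral shape constant b.
#' @param low_p_move move used on the low-p branch around the elite member:
#'   `"spiral"` (bubble-net, default) or `"encircle"`.
#' @param partitions data partitions per objective evaluation.
#' @param backend `"serial"` or `"process"` partition mapping.
#' @param cores process-pool width when `backend = "process"`.
#' @return list of class `mowoats_control`.
#' @export
mowoats_control <- function(max_it = 50L, np = 15L, max_el = 50L,
                            max_non_improve = 2L, p_threshold = 0.2,
                            spiral_b = 1, low_p_move = c("spiral", "encircle"),
                            partitions = 1L, backend = c("serial", "process"),
                            cores = 2L) {
  low_p_move <- match.arg(low_p_move)
  backend <- match.arg(backend)
  stopifnot(max_it >= 1L, np >= 2L, max_el >= 1L, max_non_improve >= 1L,
            p_threshold > 0, p_threshold < 1)
  structure(list(max_it = as.integer(max_it), np = as.integer(np),
                 max_el = as.integer(max_el),
                 max_non_improve = as.integer(max_non_improve),
                 p_threshold = p_threshold, spiral_b = spiral_b,
                 low_p_move = low_p_move, partitions = as.integer(partitions),
                 backend = backend, cores = as.integer(cores)),
            class = "mowoats_control")
}

# Draw an initial swarm: each solution's k centroids are k distinct data rows.
.init_population <- function(data, k, np) {
  n <- nrow(data)
  if (n < k) stop("need at least k data rows to initialize centroids")
  lapply(seq_len(np), function(i) {
    rows <- sample.int(n, k)
    list(centroids = data[rows, , drop = FALSE], objectives = NULL)
  })
}

# Per-feature clamp of a k x f centroid matrix to the data bounds.
.clamp <- function(cent, lower, upper) {
  cent <- pmin(pmax(cent, rep(lower, each = nrow(cent))),
               rep(upper, each = nrow(cent)))
  cent
}

.eval_solution <- function(sol, data, metric, control, data_ranks) {
  sol$objectives <- evaluate_objectives(sol$centroids, data, metric,
                                        partitions = control$partitions,
                                        backend = control$backend,
                                        data_ranks = data_ranks,
                                        cores = control$cores)
  sol
}

# One main-loop iteration over the whole swarm; returns swarm, el, changed.
.mowoats_step <- function(swarm, el, t, k, f, data, metric, control,
                          data_ranks, lower, upper) {
  changed_any <- FALSE
  for (i in seq_along(swarm)) {
    par <- woa_params(t, control$max_it, k * f)
    pos <- as.vector(t(swarm[[i]]$centroids))
    if (par$p > control$p_threshold) {
      if (max(abs(par$A)) < 1) {
        guide <- el$solutions[[sample.int(length(el$solutions), 1L)]]$centroids
        new <- woa_encircle(pos, as.vector(t(guide)), par$A, par$C)
      } else {
        j <- sample.int(length(swarm), 1L)
        guide <- swarm[[j]]$centroids
        new <- woa_encircle(pos, as.vector(t(guide)), par$A, par$C)
      }
    } else {
      guide <- el$solutions[[sample.int(length(el$solutions), 1L)]]$centroids
      new <- if (control$low_p_move == "spiral") {
        woa_spiral(pos, as.vector(t(guide)), par$l, control$spiral_b)
      } else {
        woa_encircle(pos, as.vector(t(guide)), par$A, par$C)
      }
    }
    cent <- .clamp(matrix(new, k, f, byrow = TRUE), lower, upper)
    sol <- list(centroids = cent, objectives = NULL)
    sol <- tryCatch(.eval_solution(sol, data, metric, control, data_ranks),
                    error = function(e) NULL)   # coincident centroids: skip
    if (is.null(sol)) next
    swarm[[i]] <- sol
    up <- el_update(el, sol)
    el <- up$el
    changed_any <- changed_any || up$changed
  }
  list(swarm = swarm, el = el, changed = changed_any)
}

# Stagnation-triggered crossover phase: q <= floor(np/2) whales are crossed
# with elite members (theta < 0.5) or with distinct random peers (theta >=
# 0.5), replaced, re-evaluated and offered to the elite list.
.crossover_phase <- function(swarm, el, theta, data, metric, control,
                             data_ranks) {
  np <- length(swarm)
  q <- sample.int(max(1L, np %/% 2L), 1L)
  chosen <- sample.int(np, q)
  for (i in chosen) {
    other <- if (theta < 0.5) {
      el$solutions[[sample.int(length(el$solutions), 1L)]]
    } else {
      pool <- setdiff(seq_len(np), i)
      swarm[[pool[sample.int(length(pool), 1L)]]]
    }
    off <- crossover_solutions(swarm[[i]], other)
    off <- tryCatch(.eval_solution(off, data, metric, control, data_ranks),
                    error = function(e) NULL)
    if (is.null(off)) next
    swarm[[i]] <- off
    el <- el_update(el, off)$el
  }
  list(swarm = swarm, el = el)
}

#' Fit a multi-objective whale-optimization clustering (MOWOATS)
#'
#' Searches for k cluster centroids of an expression matrix by a whale
#' optimization swarm hybridized with tabu-search memory. Candidate
#' solutions (k centroids each) are scored on three objectives at once —
#' Xie-Beni index and overall deviation (minimized) and the Simple
#' Silhouette Index (maximized) — and every mutually non-dominated solution
#' encountered is archived in a bounded elite list that guides subsequent
#' moves. When the elite list stalls for `max_non_improve` consecutive
#' iterations, a crossover phase exchanges centroid subsets between whales
#' and elite members to re-diversify the swarm. The returned fit carries the
#' full Pareto front; the single reported clustering is the front member
#' with the highest full Silhouette width.
#'
#' @param x expression matrix (genes x features), or anything accepted by
#'   [as_expression_matrix()].
#' @param k number of clusters (>= 2).
#' @param metric `"euclidean"` (default) or `"spearman"`; one metric is used
#'   by the objectives, the assignment and the validation throughout. Under
#'   `"spearman"`, centroids live in raw expression space and are
#'   rank-transformed on the fly.
#' @param control a [mowoats_control()] list.
#' @param seed integer seed; the single RNG stream drawn from it governs
#'   every stochastic choice, so equal seeds give identical fits.
#' @param true_labels optional reference partition; when given, the
#'   validation report includes the F-measure against it.
#' @return an object of class `mowoats`: a list with `labels` (per-gene
#'   cluster index), `centroids`, `objectives`, `report` (silhouette, dbi,
#'   dunn, optional f_measure), `elite` (the elite list), `front` (its
#'   objective matrix), `metric`, `k`, `control`, `seed`, `data`, `call`.
#' @seealso [select_best_solution()], [cluster_heatmap()],
#'   [silhouette_index()]
#' @examples
#' syn <- synth_expression(n_genes = 60, n_features = 5, k = 3,
#'                         separation = 8, seed = 7)
#' fit <- mowoats(syn$data, k = 3, seed = 7,
#'                control = mowoats_control(max_it = 10, np = 8))
#' table(fit$labels, syn$labels)
#' @export
mowoats <- function(x, k, metric = c("euclidean", "spearman"),
                    control = mowoats_control(), seed = NULL,
                    true_labels = NULL) {
  cl <- match.call()
  metric <- match.arg(metric)
  x <- as_expression_matrix(x)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (nrow(x) < k) stop("fewer data rows than clusters")
  if (!is.null(seed)) set.seed(as.integer(seed))
  f <- ncol(x)
  lower <- apply(x, 2L, min)
  upper <- apply(x, 2L, max)
  data_ranks <- if (metric == "spearman") rank_matrix(x) else NULL

  swarm <- .init_population(x, k, control$np)
  el <- elite_list(control$max_el)
  for (i in seq_along(swarm)) {
    swarm[[i]] <- .eval_solution(swarm[[i]], x, metric, control, data_ranks)
    el <- el_update(el, swarm[[i]])$el
  }

  stagnation <- 0L
  for (t in 0:(control$max_it - 1L)) {
    st <- .mowoats_step(swarm, el, t, k, f, x, metric, control,
                        data_ranks, lower, upper)
    swarm <- st$swarm
    el <- st$el
    stagnation <- if (st$changed) 0L else stagnation + 1L
    if (stagnation >= control$max_non_improve) {
      theta <- stats::runif(1L)
      cp <- .crossover_phase(swarm, el, theta, x, metric, control, data_ranks)
      swarm <- cp$swarm
      el <- cp$el
      stagnation <- 0L
    }
  }

  best <- select_best_solution(el, x, metric, data_ranks = data_ranks)
  report <- best$report
  if (!is.null(true_labels))
    report$f_measure <- f_measure(best$labels, true_labels)
  structure(list(labels = best$labels,
                 centroids = best$solution$centroids,
                 objectives = best$solution$objectives,
                 report = report,
                 elite = el,
                 front = el_objectives(el),
                 metric = metric, k = k, control = control,
                 seed = seed, data = x, call = cl),
            class = "mowoats")
}

#' @export
print.mowoats <- function(x, ...) {
  cat("MOWOATS clustering fit\n")
  cat(sprintf("  %d genes x %d features, k = %d, metric = %s\n",
              nrow(x$data), ncol(x$data), x$k, x$metric))
  cat(sprintf("  Pareto front: %d non-dominated solutions\n", length(x$elite)))
  cat(sprintf("  selected solution: silhouette = %.4f\n", x$report$silhouette))
  invisible(x)
}

#' @export
summary.mowoats <- function(object, ...) {
  sizes <- tabulate(object$labels, nbins = object$k)
  out <- list(k = object$k, metric = object$metric, sizes = sizes,
              objectives = object$objectives, report = object$report,
              front_size = length(object$elite))
  class(out) <- "summary.mowoats"
  out
}

#' @export
print.summary.mowoats <- function(x, ...) {
  cat(sprintf("MOWOATS fit: k = %d clusters (%s metric)\n", x$k, x$metric))
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat(sprintf("objectives: XB = %.6g  Dev = %.6g  SSI = %.6g\n",
              x$objectives[["xb"]], x$objectives[["dev"]],
              x$objectives[["ssi"]]))
  cat(sprintf("validation: silhouette = %.4f  DBI = %.4f  Dunn = %.4f\n",
              x$report$silhouette, x$report$dbi, x$report$dunn))
  if (!is.null(x$report$f_measure))
    cat(sprintf("            F-measure = %.4f\n", x$report$f_measure))
  cat(sprintf("Pareto front size: %d\n", x$front_size))
  invisible(x)
}

#' @export
coef.mowoats <- function(object, ...) object$centroids

#' Assign new expression profiles to the fitted clusters
#'
#' @param object a `mowoats` fit.
#' @param newdata matrix of profiles with the fit's feature count; defaults
#'   to the training data.
#' @param ... unused.
#' @return integer vector of 1-based cluster labels.
#' @export
predict.mowoats <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$labels)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$centroids))
    stop("newdata feature count differs from the fit")
  assign_points(newdata, object$centroids, object$metric)$i_min
}

#' Distances of each gene to its assigned centroid
#'
#' @param object a `mowoats` fit.
#' @param ... unused.
#' @return numeric vector (one value per gene) under the fit's metric.
#' @export
residuals.mowoats <- function(object, ...) {
  asg <- assign_points(object$data, object$centroids, object$metric)
  stats::setNames(asg$d1, rownames(object$data))
}

#' Plot a MOWOATS fit
#'
#' `which = "front"` draws the pairwise scatter of the elite list's three
#' objectives (the Pareto front); `which = "heatmap"` draws the
#' cluster-ordered expression heatmap of the selected solution.
#'
#' @param x a `mowoats` fit.
#' @param which `"front"` or `"heatmap"`.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.mowoats <- function(x, which = c("front", "heatmap"), ...) {
  which <- match.arg(which)
  if (which == "front") {
    graphics::pairs(x$front, main = "Pareto front (elite list)", ...)
  } else {
    ord <- order(x$labels, seq_along(x$labels))
    m <- x$data[ord, , drop = FALSE]
    pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(64)
    graphics::image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE], col = pal,
                    axes = FALSE, main = "cluster-ordered expression", ...)
  }
  invisible(x)
}
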