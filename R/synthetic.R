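#' Generate a synthetic expression dataset with known cluster structure
#'
#' Emulates the shape of normalized microarray expression tables (a few
#' hundred genes by a handful of conditions or time points) with k latent
#' groups so every pipeline stage is testable without downloads. Two profile
#' shapes are offered. `"blob"` draws k group centroids whose pairwise
#' distance is at least `separation * noise_sigma` and adds isotropic
#' Gaussian noise; group recovery difficulty is thus controlled in noise-sd
#' units. `"timecourse"` builds smooth per-group templates over the ordered
#' features (rising, falling, peaked, sinusoidal, then phase-shifted
#' variants), z-scored per group like normalized log-ratio trajectories, and
#' adds the same noise — useful for rank/Spearman tests where shape rather
#' than magnitude carries the signal. `tie_fraction` quantizes that share of
#' entries to 2 decimals so minimum-order rank ties actually occur.
#'
#' @param n_genes number of rows.
#' @param n_features number of columns.
#' @param k number of latent groups (>= 2).
#' @param weights group weights, summing to 1; uniform by default.
#' @param separation centroid spacing in units of `noise_sigma` (blob shape).
#' @param noise_sigma additive Gaussian noise sd.
#' @param shape `"blob"` or `"timecourse"`.
#' @param tie_fraction fraction of entries rounded to 2 decimals.
#' @param seed optional integer seed.
#' @return list with `data` (expression matrix with gene ids), integer
#'   `labels` (true group of each gene) and `centers` (the k group
#'   templates).
#' @export
synth_expression <- function(n_genes = 400L, n_features = 10L, k = 4L,
                             weights = NULL, separation = 10, noise_sigma = 1,
                             shape = c("blob", "timecourse"),
                             tie_fraction = 0, seed = NULL) {
  shape <- match.arg(shape)
  if (k < 2L) stop("k must be at least 2")
  if (separation <= 0) stop("separation must be positive")
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || any(weights <= 0))
    stop("weights must be k positive values")
  weights <- weights / sum(weights)
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (shape == "blob") {
    min_sep <- separation * noise_sigma
    # box scale floored at 1 so the zero-noise limit still yields distinct centroids
    half <- max(min_sep, 1) * max(1, k^(1 / n_features))
    centers <- NULL
    for (try in seq_len(1000L)) {
      cand <- matrix(stats::runif(k * n_features, -half, half), k, n_features)
      if (k < 2L || min(stats::dist(cand)) >= min_sep) { centers <- cand; break }
    }
    if (is.null(centers))
      stop("could not place group centroids at the requested separation")
  } else {
    tt <- seq(0, 1, length.out = n_features)
    base <- list(rising = tt,
                 falling = 1 - tt,
                 peaked = exp(-((tt - 0.5)^2) / 0.05),
                 sinus = sin(2 * pi * tt))
    centers <- matrix(0, k, n_features)
    for (g in seq_len(k)) {
      shape_g <- base[[((g - 1L) %% length(base)) + 1L]]
      phase <- (g - 1L) %/% length(base)
      if (phase > 0) shape_g <- sin(2 * pi * (tt * (1 + phase) + 0.13 * g))
      z <- (shape_g - mean(shape_g)) / stats::sd(shape_g)
      centers[g, ] <- z
    }
  }

  labels <- sample.int(k, n_genes, replace = TRUE, prob = weights)
  noise <- matrix(stats::rnorm(n_genes * n_features, sd = noise_sigma),
                  n_genes, n_features)
  values <- centers[labels, , drop = FALSE] + noise
  if (tie_fraction > 0) {
    m <- n_genes * n_features
    pick <- sample.int(m, ceiling(tie_fraction * m))
    values[pick] <- round(values[pick], 2L)
    # quantization alone may leave every row tie-free; guarantee at least one
    # within-row tie so the minimum-order tie path is always exercised
    ranks <- t(apply(values, 1L, rank, ties.method = "min"))
    if (!any(apply(ranks, 1L, anyDuplicated) > 0L)) {
      i <- sample.int(n_genes, 1L)
      values[i, 2L] <- values[i, 1L] <- round(values[i, 1L], 2L)
    }
  }
  data <- as_expression_matrix(values,
                               gene_ids = sprintf("g%04d", seq_len(n_genes)),
                               feature_labels = sprintf("t%02d", seq_len(n_features)))
  list(data = data, labels = labels, centers = centers)
}
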