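test_that("full silhouette reproduces hand-worked and limiting cases", {
  # two tight 1D pairs far apart
  X <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  lab <- c(1, 1, 2, 2)
  a <- 0.1; b <- (10 + 10.05) / 2  # point 0: mean distance to {10, 10.1}
  expect_equal(silhouette_index(cbind(X, 0), lab),
               mean(c((10.05 - 0.1) / 10.05, (9.95 - 0.1) / 9.95,
                      (9.95 - 0.1) / 9.95, (10.05 - 0.1) / 10.05)))

  # identical duplicated points with a far second cluster score s = 1
  Y <- rbind(matrix(0, 3, 2), matrix(10, 3, 2) + rnorm(6, sd = 0.01))
  sY <- silhouette_index(Y, rep(1:2, each = 3))
  expect_gte(sY, 0.99)

  # two singletons score 0
  expect_equal(silhouette_index(matrix(c(0, 5, 0, 5), 2, 2), c(1, 2)), 0)
  expect_error(silhouette_index(matrix(rnorm(10), 5, 2), rep(1, 5)),
               "at least 2")
})

test_that("silhouette agrees with independent references on random data", {
  skip_if_not_installed("cluster")
  set.seed(51)
  for (i in 1:25) {
    n <- sample(15:60, 1); f <- sample(2:6, 1); k <- sample(2:5, 1)
    X <- matrix(rnorm(n * f), n, f)
    lab <- sample(k, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    ref <- mean(cluster::silhouette(lab, dist(X))[, "sil_width"])
    expect_equal(silhouette_index(X, lab), ref, tolerance = 1e-9)
    expect_equal(silhouette_index(X, lab), oracle_silhouette(X, lab),
                 tolerance = 1e-9)
  }
})

test_that("Davies-Bouldin matches direct evaluation and its invariances", {
  X <- matrix(c(0, 2, 10, 12), 4, 1)
  C <- matrix(c(1, 11), 2, 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(davies_bouldin(cbind(X, 0), lab, cbind(C, 0)), 0.2)
  # points at centroids
  expect_equal(davies_bouldin(rbind(C, C), c(1, 2, 1, 2), C), 0)
  # translation invariance
  expect_equal(davies_bouldin(cbind(X + 7, 0), lab, cbind(C + 7, 0)), 0.2)
  expect_error(davies_bouldin(cbind(X, 0), lab, cbind(rbind(C[1, ], C[1, ]), 0)),
               "coincident")

  set.seed(52)
  for (i in 1:25) {
    n <- sample(15:50, 1); f <- sample(2:5, 1); k <- sample(2:4, 1)
    Xr <- matrix(rnorm(n * f), n, f)
    lab <- sample(k, n, replace = TRUE)
    if (length(unique(lab)) < k) next
    Cr <- do.call(rbind, lapply(1:k, function(g)
      colMeans(Xr[lab == g, , drop = FALSE])))
    expect_equal(davies_bouldin(Xr, lab, Cr), oracle_dbi(Xr, lab, Cr),
                 tolerance = 1e-9)
  }
})

test_that("Dunn index matches direct evaluation and its invariances", {
  X <- cbind(c(0, 1, 10, 11), 0)
  lab <- c(1, 1, 2, 2)
  expect_equal(dunn_index(X, lab), 9)
  # duplicated point changes nothing
  expect_equal(dunn_index(rbind(X, X[1, ]), c(lab, 1)), 9)
  # scale invariance
  expect_equal(dunn_index(X * 3, lab), 9)
  expect_error(dunn_index(cbind(c(0, 5), 0), c(1, 2)), "degenerate")

  set.seed(53)
  for (i in 1:25) {
    n <- sample(15:50, 1); f <- sample(2:5, 1); k <- sample(2:4, 1)
    Xr <- matrix(rnorm(n * f), n, f)
    lab <- sample(k, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(dunn_index(Xr, lab), oracle_dunn(Xr, lab), tolerance = 1e-9)
  }
})

test_that("F-measure scores class recovery through the contingency table", {
  lab <- c(1, 1, 1, 2, 2, 2)
  expect_equal(f_measure(lab, lab), 1.0)
  # relabeling invariance
  expect_equal(f_measure(c(2, 2, 2, 1, 1, 1), lab), 1.0)
  expect_equal(f_measure(3 - lab + 4, lab), 1.0)
  # classes {1,2,3|4,5,6} vs clusters {1,2,4|3,5,6}
  pred <- c(1, 1, 2, 1, 2, 2)
  expect_equal(f_measure(pred, lab), 2 / 3)
  # point-order invariance
  set.seed(54)
  p <- sample(6)
  expect_equal(f_measure(pred[p], lab[p]), 2 / 3)
  expect_error(f_measure(1:3, 1:4), "length")
})

test_that("true labels beat random relabelings on separated blobs", {
  syn <- synth_expression(n_genes = 80, n_features = 5, k = 3,
                          separation = 10, seed = 55)
  s_true <- silhouette_index(syn$data, syn$labels)
  set.seed(55)
  for (i in 1:100) {
    rnd <- sample(3, 80, replace = TRUE)
    if (length(unique(rnd)) < 2) next
    expect_gt(s_true, silhouette_index(syn$data, rnd))
  }
})

test_that("best-solution selection maximizes the full silhouette", {
  syn <- synth_expression(n_genes = 60, n_features = 4, k = 3,
                          separation = 10, seed = 56)
  X <- syn$data
  tight <- do.call(rbind, lapply(1:3, function(g)
    colMeans(X[syn$labels == g, , drop = FALSE])))
  set.seed(56)
  loose <- X[sample(60, 3), ]
  mk <- function(cen) list(centroids = cen,
                           objectives = evaluate_objectives(cen, X))
  el <- elite_list(10)
  el$solutions <- list(mk(loose), mk(tight))

  pick <- select_best_solution(el, X)
  expect_equal(pick$solution$centroids, tight)
  expect_setequal(names(pick$report), c("silhouette", "dbi", "dunn"))

  # single member
  el1 <- elite_list(10); el1$solutions <- list(mk(tight))
  expect_equal(select_best_solution(el1, X)$solution$centroids, tight)

  # invariant to archive order for distinct silhouettes
  el_rev <- elite_list(10); el_rev$solutions <- list(mk(tight), mk(loose))
  expect_equal(select_best_solution(el_rev, X)$solution$centroids, tight)

  # F-measure appended when truth is given
  with_truth <- select_best_solution(el, X, true_labels = syn$labels)
  expect_true("f_measure" %in% names(with_truth$report))
  expect_error(select_best_solution(elite_list(5), X), "empty")
})

test_that("members collapsing to one cluster are skipped with a warning", {
  syn <- synth_expression(n_genes = 40, n_features = 4, k = 2,
                          separation = 10, seed = 57)
  X <- syn$data
  # both centroids far on the same side: every point lands in one cluster
  far <- max(X) + 10
  bad <- matrix(c(rep(far, 4), rep(far + 0.5, 4)), 2, 4, byrow = TRUE)
  good <- do.call(rbind, lapply(1:2, function(g)
    colMeans(X[syn$labels == g, , drop = FALSE])))
  mk <- function(cen) list(centroids = cen,
                           objectives = c(xb = 1, dev = 1, ssi = 0.5))
  el <- elite_list(10)
  el$solutions <- list(mk(bad), mk(good))
  expect_warning(pick <- select_best_solution(el, X), "single cluster")
  expect_equal(pick$solution$centroids, good)

  el_bad <- elite_list(10); el_bad$solutions <- list(mk(bad))
  expect_error(suppressWarnings(select_best_solution(el_bad, X)),
               "no elite member")
})
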