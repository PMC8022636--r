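small_fit <- function(seed = 1, ...) {
  syn <- synth_expression(n_genes = 60, n_features = 5, k = 3,
                          separation = 8, seed = seed)
  list(syn = syn,
       fit = mowoats(syn$data, 3, seed = seed,
                     control = mowoats_control(max_it = 8, np = 6, ...)))
}

test_that("whale-move parameter draws follow the schedule", {
  set.seed(41)
  p0 <- woa_params(0, 50, 10)
  expect_equal(p0$a, 2)
  pe <- woa_params(49, 50, 10)
  expect_equal(pe$a, 2 / 50)
  expect_error(woa_params(50, 50, 10))

  for (t in c(0, 10, 25, 49)) {
    for (i in 1:200) {
      p <- woa_params(t, 50, 8)
      expect_true(all(abs(p$A) <= p$a + 1e-15))
      expect_true(all(p$C >= 0 & p$C <= 2))
      expect_true(p$l >= -1 && p$l <= 1)
      expect_true(p$p >= 0 && p$p <= 1)
    }
  }
})

test_that("encircling and spiral moves reproduce their closed forms", {
  expect_equal(woa_encircle(c(3, -1), c(5, 2), A = c(0, 0), C = c(1, 1)),
               c(5, 2))
  expect_equal(woa_encircle(c(5, 2), c(5, 2), A = c(0.7, 0.3), C = c(1, 1)),
               c(5, 2))
  expect_equal(woa_encircle(0, 2, A = 0.5, C = 1), 1)
  expect_error(woa_encircle(1:2, 1:3, 1, 1), "length")

  expect_equal(woa_spiral(c(5, 2), c(5, 2), l = 0.3), c(5, 2))
  expect_equal(woa_spiral(0, 2, l = 0, b = 1), 4)
  # l = -1: contraction by e^-1 when the cosine term is at its extreme
  d <- abs(woa_spiral(0, 2, l = -1, b = 1) - 2)
  expect_lte(d, exp(-1) * 2 + 1e-12)
  expect_error(woa_spiral(1:2, 1:3, 0), "length")
})

test_that("initial solutions are k distinct data rows", {
  set.seed(42)
  X <- matrix(rnorm(50), 10, 5)
  pop <- mowoats:::.init_population(X, 3, 20)
  expect_length(pop, 20)
  for (s in pop) {
    expect_equal(dim(s$centroids), c(3L, 5L))
    # rows are distinct members of the dataset
    expect_equal(anyDuplicated(s$centroids), 0L)
    expect_true(all(apply(s$centroids, 1, function(r)
      any(apply(X, 1, function(x) all(x == r))))))
  }
  # n = k: every solution is a permutation of the whole dataset
  pop_full <- mowoats:::.init_population(X[1:3, ], 3, 5)
  for (s in pop_full)
    expect_equal(s$centroids[order(s$centroids[, 1]), ],
                 X[1:3, ][order(X[1:3, 1]), ], ignore_attr = TRUE)
  expect_error(mowoats:::.init_population(X[1:2, ], 3, 5), "at least k")

  set.seed(7)
  a <- mowoats:::.init_population(X, 3, 4)
  set.seed(7)
  b <- mowoats:::.init_population(X, 3, 4)
  expect_identical(a, b)
})

test_that("crossover exchanges between 1 and k-1 centroid slots", {
  set.seed(43)
  s1 <- list(centroids = matrix(0, 5, 3))
  s2 <- list(centroids = matrix(1, 5, 3))
  for (i in 1:100) {
    off <- crossover_solutions(s1, s2)
    swapped <- rowSums(off$centroids) > 0
    expect_gte(sum(swapped), 1)
    expect_lte(sum(swapped), 4)
    expect_null(off$objectives)
  }
  # identical parents: offspring identical
  off_same <- crossover_solutions(s1, s1)
  expect_equal(off_same$centroids, s1$centroids)
  # k = 2 forces exactly one swapped slot
  t1 <- list(centroids = matrix(0, 2, 2))
  t2 <- list(centroids = matrix(1, 2, 2))
  off2 <- crossover_solutions(t1, t2)
  expect_equal(sort(rowSums(off2$centroids)), c(0, 2))
  expect_error(crossover_solutions(list(centroids = matrix(0, 1, 2)),
                                   list(centroids = matrix(1, 1, 2))),
               "at least 2")
})

test_that("a fitted run returns a valid, reproducible Pareto archive", {
  r1 <- small_fit(seed = 9)
  r2 <- small_fit(seed = 9)
  expect_identical(r1$fit$labels, r2$fit$labels)
  expect_identical(r1$fit$front, r2$fit$front)
  expect_identical(r1$fit$centroids, r2$fit$centroids)
  expect_equal(r1$fit$report, r2$fit$report)

  fit <- r1$fit
  expect_gte(length(fit$elite), 1L)
  # archive members are mutually non-dominated
  expect_equal(length(oracle_front(fit$front)), nrow(fit$front))
  # all archived centroids honour the per-feature data bounds
  lo <- apply(r1$syn$data, 2, min); hi <- apply(r1$syn$data, 2, max)
  for (s in fit$elite$solutions) {
    expect_true(all(s$centroids >= rep(lo, each = 3) - 1e-12))
    expect_true(all(s$centroids <= rep(hi, each = 3) + 1e-12))
  }
})

test_that("degenerate branch splits still yield valid fits", {
  # p_threshold near 0 reduces the p-branch to pure encircling
  r <- small_fit(seed = 5, p_threshold = 1e-9)
  expect_gte(length(r$fit$elite), 1L)
  expect_equal(length(oracle_front(r$fit$front)), nrow(r$fit$front))
  # near 1: spiral branch dominates
  r2 <- small_fit(seed = 5, p_threshold = 1 - 1e-9)
  expect_gte(length(r2$fit$elite), 1L)
  # encircle variant of the low-p move
  r3 <- small_fit(seed = 5, low_p_move = "encircle")
  expect_gte(length(r3$fit$elite), 1L)
})

test_that("well-separated groups are recovered", {
  set.seed(44)
  fs <- vapply(1:3, function(s) {
    r <- small_fit(seed = s)
    f_measure(r$fit$labels, r$syn$labels)
  }, numeric(1))
  expect_gte(median(fs), 0.95)
})

test_that("fit methods expose labels, centroids and predictions coherently", {
  r <- small_fit(seed = 2)
  fit <- r$fit
  expect_identical(predict(fit), fit$labels)
  expect_identical(unname(predict(fit, r$syn$data)), fit$labels)
  expect_equal(dim(coef(fit)), c(3L, 5L))
  res <- residuals(fit)
  expect_length(res, 60)
  expect_true(all(res >= 0))
  expect_output(print(fit), "MOWOATS clustering fit")
  expect_output(print(summary(fit)), "cluster sizes")
  expect_error(predict(fit, matrix(0, 2, 9)), "feature count")

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, which = "front"))
  expect_silent(plot(fit, which = "heatmap"))
})

test_that("spearman-metric fits run end to end on shape-clustered data", {
  syn <- synth_expression(n_genes = 60, n_features = 8, k = 3,
                          shape = "timecourse", noise_sigma = 0.25, seed = 6)
  fit <- mowoats(syn$data, 3, metric = "spearman", seed = 6,
                 control = mowoats_control(max_it = 8, np = 6))
  expect_length(fit$labels, 60)
  expect_gte(length(fit$elite), 1L)
  expect_true(is.finite(fit$report$silhouette))
})
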