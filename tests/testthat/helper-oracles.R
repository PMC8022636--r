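# Shared fixtures and independent oracle implementations. The oracles are
# deliberately naive (nested loops, direct definitions) and share no code
# with the package internals they check.

# Printed excerpt of a serum-response expression table: 7 genes x 6 time
# points of normalized log-ratio values.
serum_excerpt <- function() {
  txt <- c(
    "gene\tt0\tt15m\tt30m\tt1h\tt2h\tt24h",
    "W95908\t1.5962\t0.534\t-1.8179\t-0.035017\t1.8996\t-0.22469",
    "AA045003\t0.095122\t2.0874\t0.26687\t0.61037\t0.85082\t-0.76362",
    "AA044434\t0.84243\t1.359\t0.68745\t0.84243\t0.32584\t-1.9471",
    "W88572\t1.1363\t0.98137\t1.1363\t0.36156\t0.30991\t-0.67147",
    "AA059077\t0.23452\t1.6489\t1.6175\t0.61169\t0.54883\t-1.777",
    "AA035657\t0.64514\t1.2043\t1.0179\t0.64514\t0.94334\t-1.6286",
    "AA180272\t0.28406\t1.3116\t1.408\t0.70151\t0.28406\t-1.5463")
  path <- tempfile(fileext = ".tsv")
  writeLines(txt, path)
  path
}

# minimum-order rank by its definition: 1 + count of strictly smaller values
oracle_min_rank <- function(x) {
  vapply(x, function(v) 1 + sum(x < v), numeric(1))
}

# exhaustive nearest/second-nearest distance table
oracle_assign <- function(X, C, metric = "euclidean") {
  n <- nrow(X)
  i_min <- integer(n); d1 <- d2 <- numeric(n)
  for (i in seq_len(n)) {
    d <- vapply(seq_len(nrow(C)), function(k)
      profile_distance(X[i, ], C[k, ], metric), numeric(1))
    i_min[i] <- which.min(d)
    sorted <- sort(d)
    d1[i] <- sorted[1]; d2[i] <- sorted[2]
  }
  list(i_min = i_min, d1 = d1, d2 = d2)
}

# brute-force non-dominated filter over a matrix of objective rows
oracle_front <- function(M) {
  keep <- rep(TRUE, nrow(M))
  for (i in seq_len(nrow(M))) for (j in seq_len(nrow(M))) {
    if (i != j && dominates(M[j, ], M[i, ])) { keep[i] <- FALSE; break }
  }
  which(keep)
}

# textbook crowding distance, written point-by-point
oracle_crowding <- function(M) {
  m <- nrow(M)
  if (m <= 2) return(rep(Inf, m))
  cd <- numeric(m)
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    o <- order(v)
    rng <- max(v) - min(v)
    for (pos in seq_len(m)) {
      i <- o[pos]
      if (pos == 1 || pos == m) cd[i] <- Inf
      else if (rng > 0 && is.finite(cd[i]))
        cd[i] <- cd[i] + (v[o[pos + 1]] - v[o[pos - 1]]) / rng
    }
  }
  cd
}

# full silhouette from its definition, point by point
oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- Inf
    for (g in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(D[i, labels == g]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_dbi <- function(X, labels, C) {
  groups <- sort(unique(labels))
  m <- length(groups)
  S <- numeric(m)
  for (gi in seq_len(m)) {
    rows <- which(labels == groups[gi])
    S[gi] <- mean(vapply(rows, function(r)
      sqrt(sum((X[r, ] - C[groups[gi], ])^2)), numeric(1)))
  }
  total <- 0
  for (i in seq_len(m)) {
    worst <- -Inf
    for (j in seq_len(m)) {
      if (i == j) next
      Mij <- sqrt(sum((C[groups[i], ] - C[groups[j], ])^2))
      worst <- max(worst, (S[i] + S[j]) / Mij)
    }
    total <- total + worst
  }
  total / m
}

oracle_dunn <- function(X, labels) {
  D <- as.matrix(dist(X))
  groups <- sort(unique(labels))
  diam <- 0
  for (g in groups) {
    rows <- which(labels == g)
    if (length(rows) > 1) diam <- max(diam, max(D[rows, rows]))
  }
  sep <- Inf
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j <= i) next
    sep <- min(sep, min(D[labels == groups[i], labels == groups[j]]))
  }
  sep / diam
}

# random mutually-consistent objective vector (positive xb/dev, ssi in [0,1])
random_objectives <- function(m) {
  cbind(xb = runif(m, 0, 2), dev = runif(m, 0, 50), ssi = runif(m))
}
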