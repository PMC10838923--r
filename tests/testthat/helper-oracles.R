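# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths.

oracle_pearson <- function(x, y) {
  n <- length(x)
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# average-rank computation written from the order statistics, not rank()
oracle_ranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  pos <- 1L
  while (pos <= length(x)) {
    run <- pos
    while (run < length(x) && x[o[run + 1L]] == x[o[pos]]) run <- run + 1L
    r[o[pos:run]] <- mean(pos:run)
    pos <- run + 1L
  }
  r
}

oracle_spearman <- function(x, y) oracle_pearson(oracle_ranks(x), oracle_ranks(y))

oracle_euclidean_matrix <- function(P, C) {
  n <- nrow(P)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((P[i, ] - C[j, ])^2))
  D
}

oracle_spearman_matrix <- function(P, C) {
  n <- nrow(P)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- oracle_spearman(P[i, ], C[j, ])
  D
}

# affine-invariant distance via generalized eigenvalues of (A, B)
oracle_riemannian <- function(a, b) {
  lam <- eigen(solve(a) %*% b)$values
  sqrt(sum(log(Re(lam))^2))
}

# per-row extremum identification, written longhand
oracle_identify_rate <- function(D, submodel, metric) {
  want_max <- (submodel == "positive" && metric == "spearman") ||
    (submodel == "negative" && metric == "euclidean")
  hits <- 0L
  for (i in seq_len(nrow(D))) {
    best <- 1L
    for (j in seq_len(ncol(D))) {
      better <- if (want_max) D[i, j] > D[i, best] else D[i, j] < D[i, best]
      if (better) best <- j
    }
    if (best == i) hits <- hits + 1L
  }
  hits / nrow(D)
}

# Mann-Whitney U and two-sided normal-approximation p with tie correction
oracle_mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  mu <- n1 * n2 / 2
  nn <- n1 + n2
  ties <- table(c(x, y))
  sig2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  z <- (u - mu) / sqrt(sig2)
  list(u = u, p = 2 * stats::pnorm(-abs(z)))
}

# all permutations of 1..n by filtering the full product grid (independent of
# the package's recursive generator); n small only
oracle_permutations <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  g[apply(g, 1L, function(row) length(unique(row)) == n), , drop = FALSE]
}

# random cohort of genuine correlation-matrix profiles
make_cohort <- function(n_dyads, n_roi, n_time = 40, seed = 1) {
  set.seed(seed)
  prof <- function() fc_profile(matrix(rnorm(n_time * n_roi), n_time, n_roi))
  fc_cohort(replicate(n_dyads, prof(), simplify = FALSE),
            replicate(n_dyads, prof(), simplify = FALSE))
}

# cohort with prescribed edge vectors (one row per dyad)
cohort_from_edges <- function(P, C, r) {
  fc_cohort(apply(P, 1L, devectorize_upper, r = r, simplify = FALSE),
            apply(C, 1L, devectorize_upper, r = r, simplify = FALSE))
}

unclass_attrs <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

random_spd <- function(r, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(r * r), r, r)
  crossprod(m) + diag(r) * 0.5
}
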