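test_that("affine-invariant distance has its closed forms and oracle", {
  expect_equal(riemannian_distance(diag(4), exp(1) * diag(4)), 2, tolerance = 1e-12)
  for (c in c(0.1, 3)) {
    expect_equal(riemannian_distance(diag(5), c * diag(5)),
                 sqrt(5) * abs(log(c)), tolerance = 1e-12)
  }
  set.seed(71)
  for (rep in 1:5) {
    a <- random_spd(2); b <- random_spd(2)
    expect_equal(riemannian_distance(a, b), oracle_riemannian(a, b),
                 tolerance = 1e-10)
  }
})

test_that("SPD metrics satisfy the metric axioms on random triples", {
  set.seed(72)
  for (fun in list(riemannian_distance, log_euclidean_distance)) {
    for (rep in 1:4) {
      a <- random_spd(4); b <- random_spd(4); c <- random_spd(4)
      expect_equal(fun(a, a), 0, tolerance = 1e-7)
      expect_equal(fun(a, b), fun(b, a), tolerance = 1e-9)
      expect_lte(fun(a, c), fun(a, b) + fun(b, c) + 1e-9)
      expect_gt(fun(a, b), 0)
    }
  }
})

test_that("the Riemannian distance is affine invariant", {
  set.seed(73)
  for (rep in 1:4) {
    a <- random_spd(4); b <- random_spd(4)
    m <- matrix(rnorm(16), 4, 4)
    while (abs(det(m)) < 1e-3) m <- matrix(rnorm(16), 4, 4)
    expect_equal(riemannian_distance(m %*% a %*% t(m), m %*% b %*% t(m)),
                 riemannian_distance(a, b), tolerance = 1e-8)
  }
})

test_that("gaussian kernel and kernel-scale heuristic behave as specified", {
  D <- matrix(2, 3, 3); diag(D) <- 0
  expect_equal(select_epsilon(D), 4)
  expect_equal(select_epsilon(D, scale = 2), 8)
  K <- gaussian_kernel(D, 4)
  expect_equal(diag(K), rep(1, 3))
  expect_equal(K[1, 2], exp(-1))
  expect_equal(K, t(K))
  expect_error(gaussian_kernel(D, 0), "positive")
  expect_error(select_epsilon(matrix(0, 3, 3)), "zero")
  # connectivity: minimum kernel entry bounded below by exp(-max d^2 / eps)
  set.seed(74)
  Dr <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  eps <- select_epsilon(Dr)
  expect_gte(min(gaussian_kernel(Dr, eps)), exp(-max(Dr^2) / eps))
})

test_that("markov normalization yields exact row-stochasticity", {
  K <- rbind(c(1, .5), c(.5, 1))
  P <- markov_normalize(K)
  expect_equal(unclass_attrs(P), rbind(c(2/3, 1/3), c(1/3, 2/3)))
  Kc <- matrix(1, 5, 5)
  expect_true(all(abs(markov_normalize(Kc) - 0.2) < 1e-15))
  set.seed(75)
  Kr <- gaussian_kernel(as.matrix(dist(matrix(rnorm(24), 12, 2))), 1)
  expect_true(all(abs(rowSums(markov_normalize(Kr)) - 1) <= 1e-12))
})

test_that("diffusion coordinates match a dense eigensolver oracle", {
  set.seed(76)
  X <- matrix(rnorm(14), 7, 2)
  D <- as.matrix(dist(X))
  P <- markov_normalize(gaussian_kernel(D, select_epsilon(D)))
  emb <- diffusion_coords(P, l = 2)
  expect_equal(emb$trivial_eigenvalue, 1, tolerance = 1e-10)
  expect_true(all(emb$eigenvalues >= -1 - 1e-12 & emb$eigenvalues <= 1 + 1e-12))
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))
  # oracle: plain eigendecomposition of P itself (right eigenvectors)
  e <- eigen(unclass_attrs(P))
  ord <- order(Re(e$values), decreasing = TRUE)
  for (k in 1:2) {
    lam <- Re(e$values[ord[k + 1]])
    phi <- Re(e$vectors[, ord[k + 1]])
    phi <- phi / sqrt(sum(phi^2))
    expect_equal(abs(emb$coordinates[, k]), abs(lam * phi), tolerance = 1e-8)
    expect_equal(emb$eigenvalues[k], lam, tolerance = 1e-10)
  }
})

test_that("duplicated profiles embed to identical coordinates", {
  set.seed(77)
  X <- rbind(matrix(rnorm(8), 4, 2), c(0, 0), c(0, 0))
  dm <- diffusion_map(X)
  expect_equal(dm$coordinates[5, ], dm$coordinates[6, ], tolerance = 1e-10)
})

test_that("a distant profile separates along the leading coordinate", {
  X <- rbind(c(0, 0), c(0.01, 0), c(5, 0))
  dm <- diffusion_map(X)
  expect_gt(abs(dm$coordinates[3, 1] - dm$coordinates[1, 1]),
            10 * abs(dm$coordinates[2, 1] - dm$coordinates[1, 1]))
})

test_that("embedding is equivariant to input reordering up to sign", {
  set.seed(78)
  X <- matrix(rnorm(16), 8, 2)
  sig <- sample(8)
  a <- diffusion_map(X)
  b <- diffusion_map(X[sig, ])
  expect_equal(abs(b$coordinates), abs(a$coordinates[sig, ]), tolerance = 1e-8)
  expect_equal(a$eigenvalues, b$eigenvalues, tolerance = 1e-10)
})

test_that("vector profiles reject non-Euclidean metrics and SPD inputs work", {
  X <- matrix(rnorm(12), 6, 2)
  expect_error(pairwise_distances(X, "riemannian"), "euclidean")
  set.seed(79)
  mats <- replicate(4, random_spd(3), simplify = FALSE)
  D <- pairwise_distances(mats, "riemannian")
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 4))
})

test_that("dyad distance statistics match the rank-sum oracle", {
  set.seed(80)
  co <- matrix(rnorm(20), 10, 2)
  roles <- rep(c("parent", "child"), 5)
  dyads <- rep(paste0("d", 1:5), each = 2)
  st <- dyad_distance_stats(co, roles = roles, dyads = dyads)
  pidx <- which(roles == "parent"); cidx <- which(roles == "child")
  D <- as.matrix(dist(co))[pidx, cidx]
  bio <- diag(D); unrel <- D[row(D) != col(D)]
  expect_equal(st$mean_bio, mean(bio))
  expect_equal(st$mean_unrel, mean(unrel))
  expect_equal(st$se_bio, sd(bio) / sqrt(5))
  expect_equal(length(unrel), 5^2 - 5)
  or <- oracle_mann_whitney(bio, unrel)
  expect_equal(st$u_statistic, or$u)
  expect_equal(st$p_value, or$p, tolerance = 1e-10)
})

test_that("coincident dyads give zero biological distance and a tiny p", {
  n <- 8
  pts <- matrix(rnorm(2 * n, sd = 5), n, 2)
  co <- rbind(pts, pts)   # child coincides with its parent
  roles <- rep(c("parent", "child"), each = n)
  dyads <- rep(paste0("d", 1:n), 2)
  st <- dyad_distance_stats(co, roles = roles, dyads = dyads)
  expect_equal(st$mean_bio, 0)
  expect_lt(st$p_value, 0.001)
  expect_gt(st$mean_unrel, 0)
})

test_that("rank-sum rejection rate is near alpha under the null", {
  set.seed(81)
  rej <- replicate(200, {
    co <- matrix(rnorm(16), 8, 2)
    st <- dyad_distance_stats(co, roles = rep(c("parent", "child"), 4),
                              dyads = rep(paste0("d", 1:4), each = 2))
    st$p_value < 0.05
  })
  expect_lt(mean(rej), 0.15)   # dependence among unrelated pairs inflates mildly
})
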