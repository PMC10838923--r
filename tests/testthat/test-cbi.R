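test_that("edgewise Spearman matches rank oracles on constructed edges", {
  # 5 dyads, 3 ROIs = 3 edges with prescribed values
  P <- cbind(c(.1, .2, .3, .4, .5),       # edge 1
             c(.1, .2, .3, .4, .5),       # edge 2: child = reversed
             c(.05, .1, .15, .2, .25))    # edge 3: oracle-checked
  C <- cbind(c(.1, .2, .3, .4, .5),
             c(.5, .4, .3, .2, .1),
             c(.3, .1, .4, .2, .5))
  co <- cohort_from_edges(P, C, r = 3)
  sel <- edgewise_spearman(co)
  expect_equal(sel$rho[1], 1)
  expect_equal(sel$rho[2], -1)
  expect_equal(sel$rho[3], oracle_spearman(P[, 3], C[, 3]), tolerance = 1e-12)
})

test_that("edgewise rho and t-approximation p agree with cor.test", {
  co <- make_cohort(7, 8, seed = 41)
  sel <- edgewise_spearman(co)
  P <- t(sapply(co$parents, vectorize_upper))
  C <- t(sapply(co$children, vectorize_upper))
  for (e in seq_len(ncol(P))) {
    ct <- suppressWarnings(
      stats::cor.test(P[, e], C[, e], method = "spearman", exact = FALSE))
    expect_equal(sel$rho[e], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(sel$p[e], ct$p.value, tolerance = 1e-10)
  }
})

test_that("exact permutation p-values match brute-force enumeration", {
  co <- make_cohort(5, 4, seed = 42)
  sel <- edgewise_spearman(co, p_method = "exact")
  P <- t(sapply(co$parents, vectorize_upper))
  C <- t(sapply(co$children, vectorize_upper))
  perms <- oracle_permutations(5)
  for (e in seq_len(ncol(P))) {
    obs <- oracle_spearman(P[, e], C[, e])
    null <- apply(perms, 1, function(s) oracle_spearman(P[, e], C[s, e]))
    expect_equal(sel$p[e], mean(abs(null) >= abs(obs) - 1e-12), tolerance = 1e-12)
  }
})

test_that("selection masks obey the threshold rule and exclude constants", {
  co <- make_cohort(8, 10, seed = 43)
  # plant a constant edge across dyads in the parents
  for (k in seq_along(co$parents)) co$parents[[k]][1, 2] <- co$parents[[k]][2, 1] <- 0.4
  expect_warning(sel <- edgewise_spearman(co), "constant")
  expect_equal(sel$n_excluded, 1)
  expect_false(sel$pos[1] || sel$neg[1])          # edge (1,2) is position 1
  expect_true(all(sel$p[sel$pos] < sel$alpha & sel$rho[sel$pos] > 0))
  expect_true(all(sel$p[sel$neg] < sel$alpha & sel$rho[sel$neg] < 0))
  expect_false(any(sel$pos & sel$neg))
})

test_that("feature vectors are direct lookups into the profiles", {
  co <- simulate_cohort(n_dyads = 8, n_roi = 12, coupling = 1.5,
                        noise_sd = 0.1, seed = 44)
  sel <- edgewise_spearman(co)
  fv <- feature_vectors(co, sel, "positive")
  expect_equal(dim(fv$parents), c(8, sum(sel$pos)))
  idx <- edge_index(12)
  for (d in c(1, 5)) for (k in seq_along(fv$edges)) {
    e <- fv$edges[k]
    expect_identical(fv$parents[d, k], co$parents[[d]][idx$i[e], idx$j[e]])
    expect_identical(fv$children[d, k], co$children[[d]][idx$i[e], idx$j[e]])
  }
})

test_that("an empty mask raises a named error identifying the sub-model", {
  co <- make_cohort(6, 6, seed = 45)
  sel <- edgewise_spearman(co, alpha = 1e-9)
  expect_error(feature_vectors(co, sel, "negative"),
               "empty_feature_mask.*negative")
})

test_that("distance matrices match nested-loop oracles", {
  set.seed(46)
  fv <- list(parents = matrix(rnorm(20), 4, 5),
             children = matrix(rnorm(20), 4, 5), submodel = "positive")
  eu <- cbi_distance(fv, "euclidean")
  sp <- cbi_distance(fv, "spearman")
  expect_equal(unclass_attrs(eu), oracle_euclidean_matrix(fv$parents, fv$children),
               tolerance = 1e-12)
  expect_equal(unclass_attrs(sp), oracle_spearman_matrix(fv$parents, fv$children),
               tolerance = 1e-12)
  # identical vectors: distance 0, correlation 1
  fv2 <- list(parents = fv$parents, children = fv$parents, submodel = "positive")
  expect_equal(diag(cbi_distance(fv2, "euclidean")), rep(0, 4), tolerance = 1e-12)
  expect_equal(diag(cbi_distance(fv2, "spearman")), rep(1, 4), tolerance = 1e-12)
  # hand arithmetic
  fv3 <- list(parents = rbind(c(1, 2, 3)), children = rbind(c(1, 2, 4)),
              submodel = "positive")
  expect_equal(as.numeric(cbi_distance(fv3, "euclidean")), 1)
  expect_error(cbi_distance(list(parents = rbind(1), children = rbind(1),
                                 submodel = "positive"), "spearman"),
               "width >= 2")
})

test_that("all four extremum rules agree with a brute-force enumerator", {
  m <- rbind(c(5, 1, 1), c(1, 6, 1), c(1, 1, 0.5))
  id <- suppressWarnings(cbi_identify(m, "negative", "euclidean"))  # row-3 tie
  expect_equal(id$hits, c(TRUE, TRUE, FALSE))
  expect_equal(id$rate, 2 / 3)
  set.seed(47)
  for (rep in 1:5) {
    D <- matrix(rnorm(36), 6, 6)
    for (sm in c("positive", "negative")) for (met in c("euclidean", "spearman")) {
      expect_equal(cbi_identify(D, sm, met)$rate,
                   oracle_identify_rate(D, sm, met))
    }
  }
})

test_that("cbi fit is equivariant under simultaneous dyad reordering", {
  co <- simulate_cohort(n_dyads = 7, n_roi = 14, coupling = 1.5,
                        noise_sd = 0.15, seed = 48)
  fit <- suppressWarnings(cbi(co))
  sig <- c(4, 2, 7, 1, 6, 3, 5)
  co2 <- fc_cohort(co$parents[sig], co$children[sig])
  fit2 <- suppressWarnings(cbi(co2))
  expect_equal(fit2$rates$rate, fit$rates$rate)
  expect_equal(sort(fit2$features$rho), sort(fit$features$rho))
})

test_that("coef.cbi lists selected edges with their statistics", {
  co <- simulate_cohort(n_dyads = 8, n_roi = 10, coupling = 1.5,
                        noise_sd = 0.1, seed = 49)
  fit <- suppressWarnings(cbi(co))
  tab <- coef(fit)
  expect_equal(nrow(tab), sum(fit$features$pos) + sum(fit$features$neg))
  expect_true(all(tab$p < fit$alpha))
  expect_true(all(tab$i < tab$j))
  expect_true(all((tab$sign == "positive") == (tab$rho > 0)))
})
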