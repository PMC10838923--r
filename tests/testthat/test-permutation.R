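test_that("label shuffling has one expected fixed point regardless of data", {
  co <- make_cohort(6, 10, seed = 51)
  fit <- suppressWarnings(cbi(co, alpha = 0.4))  # permissive threshold so both sub-models exist
  rep <- cbi_label_permutation(fit, n_perm = 3000, seed = 2)
  for (nm in names(rep))
    expect_lt(abs(rep[[nm]]$mean_rate * 6 - 1), 0.12)
})

test_that("child-only shuffling matches independent two-set shuffling in law", {
  co <- make_cohort(6, 10, seed = 52)
  fit <- suppressWarnings(cbi(co, alpha = 0.4))
  nm <- names(fit)[names(fit) %in% c("positive", "negative")][1]
  id <- fit[[nm]]$euclidean$id
  one <- cbi_label_permutation(fit, n_perm = 4000, seed = 3)[[paste0(nm, "_euclidean")]]
  # paired scheme: shuffle parents and children independently as stated
  set.seed(4)
  both <- replicate(4000, {
    sp <- sample.int(6); sc <- sample.int(6)
    mean(id$matches[sp] == sc)
  })
  expect_lt(abs(mean(both) - one$mean_rate), 0.03)
  expect_lt(abs(sd(both) - sd(one$per_perm_rates)), 0.03)
})

test_that("exhaustive label permutation matches brute-force enumeration", {
  co <- make_cohort(5, 8, seed = 53)
  fit <- suppressWarnings(cbi(co, alpha = 0.8))
  rep <- cbi_label_permutation(fit, exact = TRUE)
  perms <- oracle_permutations(5)
  for (nm in names(rep)) {
    expect_equal(rep[[nm]]$n_perm, factorial(5))
    parts <- strsplit(nm, "_")[[1]]
    id <- fit[[parts[1]]][[parts[2]]]$id
    rates <- apply(perms, 1, function(sig) mean(id$matches == sig))
    expect_equal(sort(rep[[nm]]$per_perm_rates), sort(rates))
    # the exhaustive mean is exactly 1/n by the fixed-point identity
    expect_equal(rep[[nm]]$mean_rate, 1 / 5, tolerance = 1e-12)
  }
})

test_that("permutation reports are internally consistent and deterministic", {
  co <- simulate_cohort(n_dyads = 5, n_roi = 10, coupling = 1.2,
                        noise_sd = 0.2, seed = 54)
  a <- suppressWarnings(cbi_feature_permutation(co, n_perm = 50, seed = 11))
  b <- suppressWarnings(cbi_feature_permutation(co, n_perm = 50, seed = 11))
  for (nm in names(a)) {
    expect_identical(a[[nm]]$per_perm_rates, b[[nm]]$per_perm_rates)
    r <- a[[nm]]
    expect_equal(r$mean_rate, mean(r$per_perm_rates))
    expect_equal(r$max_rate, max(r$per_perm_rates))
    expect_equal(r$max_recurrence, sum(r$per_perm_rates == r$max_rate))
    expect_equal(r$p_value,
                 mean(r$per_perm_rates >= r$observed_rate - 1e-12))
  }
})

test_that("feature permutation reruns selection on the shuffled pairing", {
  # strongly coupled cohort: original masks identify perfectly, shuffled
  # masks should not do so systematically
  co <- simulate_cohort(n_dyads = 8, n_roi = 16, coupling = 1.5,
                        noise_sd = 0.1, seed = 55)
  rep <- suppressWarnings(cbi_feature_permutation(co, n_perm = 300, seed = 12))
  for (nm in names(rep)) {
    expect_gte(rep[[nm]]$observed_rate, 0.75)
    expect_lt(rep[[nm]]$mean_rate, 0.5)
  }
})

test_that("degenerate-mask permutations are scored as zero and counted", {
  co <- make_cohort(6, 8, seed = 56)
  rep <- suppressWarnings(
    cbi_feature_permutation(co, n_perm = 60, seed = 13, alpha = 1e-5))
  deg <- attr(rep, "degenerate")
  expect_true(all(deg > 0))
  if (length(rep) > 0)
    expect_true(all(vapply(rep, function(r) mean(r$per_perm_rates), 1) < 0.2))
})

test_that("conservative p-values apply the (k+1)/(B+1) correction", {
  co <- simulate_cohort(n_dyads = 6, n_roi = 10, coupling = 1.5,
                        noise_sd = 0.1, seed = 57)
  fit <- suppressWarnings(cbi(co))
  plain <- suppressWarnings(cbi_label_permutation(fit, n_perm = 100, seed = 14))
  cons <- suppressWarnings(cbi_label_permutation(fit, n_perm = 100, seed = 14, conservative = TRUE))
  for (nm in names(plain)) {
    k <- sum(plain[[nm]]$per_perm_rates >= plain[[nm]]$observed_rate - 1e-12)
    expect_equal(plain[[nm]]$p_value, k / 100)
    expect_equal(cons[[nm]]$p_value, (k + 1) / 101)
  }
})
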