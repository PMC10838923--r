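#' Label-shuffling permutation test for a CBI fit (test 1)
#'
#' Holds the selected feature masks fixed and repeatedly re-pairs parents and
#' children at random, recomputing the identification rate under each false
#' pairing. Shuffling both sets independently and shuffling only the child
#' order induce the same uniform distribution over diagonal pairings; the
#' simpler scheme is used. A single stream of permutations is scored under
#' all four sub-model-by-metric rules. The p-value per rule is the fraction
#' of permutations whose rate is at least the observed one; under shuffling
#' the expected number of identified couples is the fixed-point count of a
#' uniform permutation, i.e. exactly 1 (rate \eqn{1/n}) whenever each row has
#' a unique extremum.
#'
#' @param fit A [cbi()] fit.
#' @param n_perm Number of permutations (default 5000).
#' @param seed Optional integer seed.
#' @param exact Enumerate all \eqn{n!} pairings instead (n <= 8).
#' @param conservative Use \eqn{(k+1)/(B+1)} p-values.
#' @return Object of class `"cbi_permutation"`: named list of
#'   `"permutation_report"`s, keyed `positive_euclidean`,
#'   `positive_spearman`, `negative_euclidean`, `negative_spearman`
#'   (only available sub-models).
#' @examples
#' co <- simulate_cohort(n_dyads = 6, n_roi = 16, coupling = 1.5,
#'                       noise_sd = 0.1, seed = 4)
#' cbi_label_permutation(cbi(co), n_perm = 200, seed = 1)
#' @export
cbi_label_permutation <- function(fit, n_perm = 5000, seed = NULL,
                                  exact = FALSE, conservative = FALSE) {
  stopifnot(inherits(fit, "cbi"))
  n <- fit$n_dyads
  perms <- permutation_stream(n, n_perm, seed, exact)
  sig <- do.call(rbind, perms)                   # B x n matrix of pairings
  out <- list()
  for (sm in c("positive", "negative")) {
    if (is.null(fit[[sm]])) next
    for (met in c("euclidean", "spearman")) {
      id <- fit[[sm]][[met]]$id
      rates <- rowMeans(sig == matrix(id$matches, nrow(sig), n, byrow = TRUE))
      out[[paste(sm, met, sep = "_")]] <- permutation_report(
        observed = id$rate, rates = rates, seed = seed,
        conservative = conservative, label = paste(sm, met, "(labels)"))
    }
  }
  structure(out, class = "cbi_permutation", test = "labels", seed = seed)
}

#' Feature-reselection permutation test for a CBI fit (test 2)
#'
#' On each permutation the dyad pairing is shuffled and the edgewise Spearman
#' selection is rerun on the shuffled pairing, yielding randomized feature
#' masks; the original (unshuffled) parent and child sets are then represented
#' by those masks and identification is scored on the true diagonal. Low mean
#' and maximum rates (and low recurrence of the maximum) indicate that the
#' original masks carry dyad-specific information rather than generic
#' structure. Permutations whose mask is empty, or too narrow for the
#' Spearman metric (width < 2), score rate 0 for the affected rules and are
#' counted: dropping them would bias the null.
#'
#' @param cohort An [fc_cohort()].
#' @param n_perm Number of permutations (default 5000).
#' @param seed Optional integer seed.
#' @param alpha Edgewise threshold used on every permutation (default 0.05).
#' @param conservative Use \eqn{(k+1)/(B+1)} p-values.
#' @return Object of class `"cbi_permutation"` as in
#'   [cbi_label_permutation()], with attribute `degenerate`: per sub-model,
#'   the count of permutations with an empty or width-1 mask.
#' @export
cbi_feature_permutation <- function(cohort, n_perm = 5000, seed = NULL,
                                    alpha = 0.05, conservative = FALSE) {
  stopifnot(inherits(cohort, "fc_cohort"))
  n <- cohort$n_dyads
  fit <- cbi(cohort, alpha = alpha)
  P <- cohort_edge_matrix(cohort, "parents")
  C <- cohort_edge_matrix(cohort, "children")
  Rp <- centered_col_ranks(P)
  Rc <- centered_col_ranks(C)
  denom <- sqrt(colSums(Rp^2) * colSums(Rc^2))
  ok <- denom > 0

  if (!is.null(seed)) set.seed(as.integer(seed))
  combos <- c("positive_euclidean", "positive_spearman",
              "negative_euclidean", "negative_spearman")
  rates <- matrix(0, n_perm, 4L, dimnames = list(NULL, combos))
  degenerate <- c(positive = 0L, negative = 0L)
  rows <- seq_len(n)
  for (b in seq_len(n_perm)) {
    tau <- sample.int(n)
    rho <- rep(NA_real_, ncol(P))
    rho[ok] <- colSums(Rp[, ok, drop = FALSE] * Rc[tau, ok, drop = FALSE]) / denom[ok]
    rho <- pmin(pmax(rho, -1), 1)
    p <- spearman_p_t(rho, n)
    sig <- is.finite(p) & p < alpha
    for (sm in c("positive", "negative")) {
      mask <- if (sm == "positive") sig & rho > 0 else sig & rho < 0
      m <- sum(mask)
      if (m == 0L || m == 1L) {
        if (m == 0L) {
          degenerate[sm] <- degenerate[sm] + 1L
          next                                  # both metrics stay at rate 0
        }
        degenerate[sm] <- degenerate[sm] + 1L   # width 1: spearman undefined
      }
      Pm <- P[, mask, drop = FALSE]
      Cm <- C[, mask, drop = FALSE]
      d2 <- outer(rowSums(Pm^2), rowSums(Cm^2), "+") - 2 * tcrossprod(Pm, Cm)
      eu_rule <- if (sm == "positive") -d2 else d2
      rates[b, paste0(sm, "_euclidean")] <-
        mean(max.col(eu_rule, ties.method = "first") == rows)
      if (m >= 2L) {
        S <- pair_spearman(Pm, Cm)
        sp_rule <- if (sm == "positive") S else -S
        rates[b, paste0(sm, "_spearman")] <-
          mean(max.col(sp_rule, ties.method = "first") == rows)
      }
    }
  }

  out <- list()
  for (combo in combos) {
    parts <- strsplit(combo, "_")[[1L]]
    if (is.null(fit[[parts[1L]]])) next
    observed <- fit[[parts[1L]]][[parts[2L]]]$id$rate
    out[[combo]] <- permutation_report(
      observed = observed, rates = rates[, combo], seed = seed,
      conservative = conservative,
      label = paste(parts[1L], parts[2L], "(features)"))
  }
  structure(out, class = "cbi_permutation", test = "features",
            degenerate = degenerate, seed = seed)
}

#' @export
print.cbi_permutation <- function(x, ...) {
  cat("CBI permutation test (", attr(x, "test"), " shuffled, ",
      x[[1L]]$n_perm, " permutations)\n", sep = "")
  for (nm in names(x)) {
    r <- x[[nm]]
    cat(sprintf("  %-19s observed %.3f | mean %.4f | max %.3f (x%d) | p = %.4g\n",
                nm, r$observed_rate, r$mean_rate, r$max_rate,
                r$max_recurrence, r$p_value))
  }
  deg <- attr(x, "degenerate")
  if (!is.null(deg) && any(deg > 0))
    cat("  degenerate-mask permutations: positive ", deg[["positive"]],
        ", negative ", deg[["negative"]], "\n", sep = "")
  invisible(x)
}
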