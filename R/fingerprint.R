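#' Pearson similarity matrix between two sets of FC profiles
#'
#' Entry \eqn{(i, j)} is the Pearson correlation between the vectorized
#' (strict upper triangle) profile of target \eqn{i} and database profile
#' \eqn{j}. Including the symmetric duplicate entries would weight every edge
#' twice uniformly and leave the correlation unchanged.
#'
#' @param targets,database Lists of FC profile matrices of equal length and
#'   equal ROI count.
#' @return Numeric n-by-n matrix with entries in \eqn{[-1, 1]}.
#' @export
similarity_matrix <- function(targets, database) {
  if (length(targets) != length(database))
    stop("target and database sets must have equal size")
  rt <- vapply(targets, nrow, integer(1))
  rd <- vapply(database, nrow, integer(1))
  if (length(unique(c(rt, rd))) != 1L)
    stop("all profiles must share the same ROI count")
  vt <- vapply(targets, vectorize_upper, numeric(rt[1] * (rt[1] - 1) / 2))
  vd <- vapply(database, vectorize_upper, numeric(rt[1] * (rt[1] - 1) / 2))
  stats::cor(vt, vd)
}

# per-row extremum identification shared by fingerprint and CBI
identify_rows <- function(values, rule = c("max", "min")) {
  rule <- match.arg(rule)
  if (!all(is.finite(values))) stop("matrix contains non-finite entries")
  n <- nrow(values)
  matches <- integer(n)
  for (i in seq_len(n)) {
    row <- values[i, ]
    ext <- if (rule == "max") max(row) else min(row)
    hit_cols <- which(row == ext)
    if (length(hit_cols) > 1L)
      warning("tie in row ", i, "; lowest column index used")
    matches[i] <- hit_cols[1L]
  }
  hits <- matches == seq_len(n)
  list(matches = matches, hits = hits, rate = mean(hits), rule = rule)
}

#' Fingerprint identification between parent and child profile sets
#'
#' Adapts fingerprint-style identification to two index-aligned sets: the
#' most similar database profile to each target (by whole-connectome Pearson
#' similarity) is its predicted counterpart, and a dyad is identified when the
#' prediction lies on the diagonal. Both directions are evaluated: children
#' as targets against the parent database and the reverse.
#'
#' @param cohort An [fc_cohort()].
#' @param direction `"both"` (default), `"child-to-parent"` (children are the
#'   targets) or `"parent-to-child"`.
#' @return Object of class `"fingerprint"`: list with the similarity matrix
#'   `similarity` (rows = parents, columns = children) and per-direction
#'   identification results (`matches`, `hits`, `rate`).
#' @examples
#' co <- simulate_cohort(n_dyads = 5, n_roi = 16, individual_strength = 1,
#'                       seed = 1)
#' fingerprint(co)
#' @export
fingerprint <- function(cohort,
                        direction = c("both", "child-to-parent", "parent-to-child")) {
  stopifnot(inherits(cohort, "fc_cohort"))
  direction <- match.arg(direction)
  sim <- similarity_matrix(cohort$parents, cohort$children)
  out <- list(similarity = sim, dyad_ids = cohort$dyad_ids,
              n_dyads = cohort$n_dyads, direction = direction)
  if (direction %in% c("both", "parent-to-child"))
    out$parent_to_child <- identify_rows(sim, "max")
  if (direction %in% c("both", "child-to-parent"))
    out$child_to_parent <- identify_rows(t(sim), "max")
  class(out) <- "fingerprint"
  out
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("Fingerprint identification (", x$n_dyads, " dyads)\n", sep = "")
  fmt <- function(id) sprintf("%d/%d dyads (%.1f%%)",
                              sum(id$hits), length(id$hits), 100 * id$rate)
  if (!is.null(x$parent_to_child))
    cat("  parent -> child: ", fmt(x$parent_to_child), "\n", sep = "")
  if (!is.null(x$child_to_parent))
    cat("  child -> parent: ", fmt(x$child_to_parent), "\n", sep = "")
  invisible(x)
}

#' Permutation test for a fingerprint identification rate
#'
#' Repeats the identification while assigning false identities: on each
#' permutation the database identities are uniformly shuffled and the rate of
#' diagonal matches under the shuffled pairing is recorded. The p-value is
#' the fraction of permutations whose rate is at least the observed one.
#'
#' @param fp A `"fingerprint"` fit from [fingerprint()].
#' @param direction Which direction's rate to test (must be present in `fp`).
#' @param n_perm Number of permutations (default 5000); ignored when
#'   `exact = TRUE`.
#' @param seed Optional seed for the permutation stream.
#' @param exact Enumerate all \eqn{n!} pairings instead of sampling
#'   (only for \eqn{n \le 8}).
#' @param conservative Use the \eqn{(k+1)/(B+1)} p-value instead of \eqn{k/B}.
#' @return Object of class `"permutation_report"` (see [cbi_label_permutation()]).
#' @export
fingerprint_permutation <- function(fp,
                                    direction = c("parent-to-child", "child-to-parent"),
                                    n_perm = 5000, seed = NULL, exact = FALSE,
                                    conservative = FALSE) {
  stopifnot(inherits(fp, "fingerprint"))
  direction <- match.arg(direction)
  id <- if (direction == "parent-to-child") fp$parent_to_child else fp$child_to_parent
  if (is.null(id)) stop("direction ", direction, " was not run in this fit")
  perms <- permutation_stream(fp$n_dyads, n_perm, seed, exact)
  rates <- vapply(perms, function(sig) mean(id$matches == sig), numeric(1))
  permutation_report(observed = id$rate, rates = rates, seed = seed,
                     conservative = conservative,
                     label = paste0("fingerprint ", direction))
}

# list of permutations: sampled, or exhaustive when exact
permutation_stream <- function(n, n_perm, seed = NULL, exact = FALSE) {
  if (exact) {
    if (n > 8L) stop("exact enumeration supported for n <= 8 only")
    return(asplit(all_permutations(n), 1L))
  }
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  lapply(seq_len(n_perm), function(b) sample.int(n))
}

# all n! permutations of 1..n, one per row
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(rep.int(k, nrow(sub)), sub + (sub >= k))
  }))
}

permutation_report <- function(observed, rates, seed = NULL,
                               conservative = FALSE, label = "") {
  k <- sum(rates >= observed - 1e-12)
  B <- length(rates)
  p <- if (conservative) (k + 1) / (B + 1) else k / B
  mx <- max(rates)
  structure(
    list(observed_rate = observed, n_perm = B, per_perm_rates = rates,
         mean_rate = mean(rates), max_rate = mx,
         max_recurrence = sum(rates >= mx - 1e-12),
         p_value = p, seed = seed, conservative = conservative, label = label),
    class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat("Permutation test", if (nzchar(x$label)) paste0(" [", x$label, "]"), "\n",
      sep = "")
  cat(sprintf("  observed rate  %.4f\n", x$observed_rate))
  cat(sprintf("  permutations   %d (mean rate %.4f, max %.4f recurring %d times)\n",
              x$n_perm, x$mean_rate, x$max_rate, x$max_recurrence))
  cat(sprintf("  p-value        %.4g%s\n", x$p_value,
              if (x$conservative) " (conservative)" else ""))
  invisible(x)
}
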