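#' Cross-group edgewise Spearman feature selection
#'
#' For every edge (ROI-to-ROI connection, "feature"), the parents' values
#' across dyads are rank-correlated with the index-aligned children's values.
#' Edges with two-sided \eqn{p < alpha} form the positive (\eqn{\rho > 0}) and
#' negative (\eqn{\rho < 0}) feature masks of the CBI sub-models. No
#' multiple-comparison correction is applied to the edgewise tests; the CBI
#' model's validity is instead established by its permutation tests, where an
#' abundance of false-positive features surfaces as a high p-value.
#'
#' @param cohort An [fc_cohort()] with at least 4 dyads.
#' @param alpha Two-sided significance threshold (default 0.05).
#' @param p_method `"t-approximation"` (two-sided, df = n - 2; the standard
#'   choice at n = 13) or `"exact"` (full enumeration of rank permutations,
#'   n <= 9 only). Ties receive average ranks.
#' @return Object of class `"cbi_features"`: list with per-edge `rho` and `p`
#'   vectors (length \eqn{r(r-1)/2}, [edge_index()] order), logical masks
#'   `pos` and `neg`, `alpha`, `n_dyads`, `n_roi`, and `n_excluded`, the
#'   number of edges constant across dyads in either set (undefined rank
#'   correlation; excluded from both masks).
#' @examples
#' co <- simulate_cohort(n_dyads = 8, n_roi = 12, seed = 2)
#' sel <- edgewise_spearman(co)
#' sum(sel$pos); sum(sel$neg)
#' @export
edgewise_spearman <- function(cohort, alpha = 0.05,
                              p_method = c("t-approximation", "exact")) {
  stopifnot(inherits(cohort, "fc_cohort"))
  p_method <- match.arg(p_method)
  n <- cohort$n_dyads
  if (n < 4L) stop("need at least 4 dyads for meaningful edgewise p-values")
  P <- cohort_edge_matrix(cohort, "parents")
  C <- cohort_edge_matrix(cohort, "children")
  sp <- spearman_columns(P, C, p_method = p_method)
  excluded <- !is.finite(sp$rho)
  if (any(excluded))
    warning(sum(excluded), " edge(s) constant across dyads; excluded from both masks")
  sig <- is.finite(sp$p) & sp$p < alpha & !excluded
  structure(
    list(rho = sp$rho, p = sp$p,
         pos = sig & sp$rho > 0, neg = sig & sp$rho < 0,
         alpha = alpha, n_dyads = n, n_roi = cohort$n_roi,
         n_excluded = sum(excluded), p_method = p_method),
    class = "cbi_features")
}

#' @export
print.cbi_features <- function(x, ...) {
  cat("Edgewise Spearman feature selection (alpha = ", x$alpha, ", ",
      x$p_method, ")\n", sep = "")
  cat("  ", length(x$rho), " edges over ", x$n_dyads, " dyads: ",
      sum(x$pos), " positive, ", sum(x$neg), " negative features",
      if (x$n_excluded) paste0(" (", x$n_excluded, " constant edges excluded)"),
      "\n", sep = "")
  invisible(x)
}

# vectorized Spearman over paired columns of two n x E matrices
spearman_columns <- function(P, C, p_method = "t-approximation") {
  n <- nrow(P)
  Rp <- centered_col_ranks(P)
  Rc <- centered_col_ranks(C)
  ssp <- colSums(Rp^2)
  ssc <- colSums(Rc^2)
  denom <- sqrt(ssp * ssc)
  rho <- ifelse(denom > 0, colSums(Rp * Rc) / denom, NA_real_)
  rho <- pmin(pmax(rho, -1), 1)
  rho[denom == 0] <- NA_real_
  p <- if (p_method == "exact") exact_spearman_p(Rp, Rc, rho)
       else spearman_p_t(rho, n)
  list(rho = rho, p = p)
}

centered_col_ranks <- function(X) {
  R <- apply(X, 2L, rank)            # average ranks for ties
  R - (nrow(X) + 1) / 2              # tie-averaged ranks keep the mean at (n+1)/2
}

# two-sided p via the t transform, df = n - 2; |rho| = 1 maps to p = 0
spearman_p_t <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  ok <- is.finite(rho)
  r2 <- rho[ok]^2
  p[ok] <- ifelse(r2 >= 1, 0, {
    tt <- abs(rho[ok]) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
    2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  })
  p
}

.perm_cache <- new.env(parent = emptyenv())

cached_permutations <- function(n) {
  key <- as.character(n)
  if (is.null(.perm_cache[[key]])) .perm_cache[[key]] <- all_permutations(n)
  .perm_cache[[key]]
}

# exact two-sided p by enumerating all n! pairings of the observed ranks
exact_spearman_p <- function(Rp, Rc, rho) {
  n <- nrow(Rp)
  if (n > 9L) stop("exact Spearman p-values supported for n <= 9 only")
  perms <- cached_permutations(n)
  p <- rep(NA_real_, length(rho))
  for (e in which(is.finite(rho))) {
    a <- Rp[, e]; b <- Rc[, e]
    null_num <- matrix(b[perms], nrow(perms)) %*% a
    null_rho <- null_num / sqrt(sum(a^2) * sum(b^2))
    p[e] <- mean(abs(null_rho) >= abs(rho[e]) - 1e-12)
  }
  p
}

#' Feature-vector representations of a cohort's subjects
#'
#' Restricts every subject's own edge vector to the selected features of one
#' sub-model, stacking parents and children into \eqn{n \times m} matrices
#' whose aligned rows belong to the same dyad.
#'
#' @param cohort An [fc_cohort()].
#' @param features A [edgewise_spearman()] selection.
#' @param submodel `"positive"` or `"negative"`.
#' @return Object of class `"cbi_vectors"`: list with matrices `parents`,
#'   `children`, the selected `edges` (positions in [edge_index()] order),
#'   and `submodel`.
#' @export
feature_vectors <- function(cohort, features, submodel = c("positive", "negative")) {
  stopifnot(inherits(cohort, "fc_cohort"), inherits(features, "cbi_features"))
  submodel <- match.arg(submodel)
  mask <- if (submodel == "positive") features$pos else features$neg
  if (!any(mask))
    stop("empty_feature_mask: no ", submodel,
         " features selected at alpha = ", features$alpha,
         "; the ", submodel, " sub-model is unavailable")
  idx <- which(mask)
  structure(
    list(parents = cohort_edge_matrix(cohort, "parents")[, idx, drop = FALSE],
         children = cohort_edge_matrix(cohort, "children")[, idx, drop = FALSE],
         edges = idx, submodel = submodel),
    class = "cbi_vectors")
}

#' Parents-by-children distance matrix for a CBI sub-model
#'
#' Entry \eqn{(i, j)} compares parent \eqn{i}'s feature vector with child
#' \eqn{j}'s: the Euclidean distance or the Spearman rank correlation.
#'
#' @param fv A [feature_vectors()] object, or a list with numeric matrices
#'   `parents` and `children` of matching width.
#' @param metric `"euclidean"` or `"spearman"`.
#' @return Numeric n-by-n matrix with attributes `metric` and `submodel`.
#' @export
cbi_distance <- function(fv, metric = c("euclidean", "spearman")) {
  metric <- match.arg(metric)
  P <- fv$parents; C <- fv$children
  if (ncol(P) != ncol(C)) stop("parent and child vector widths differ")
  D <- if (metric == "euclidean") pair_euclidean(P, C) else pair_spearman(P, C)
  attr(D, "metric") <- metric
  attr(D, "submodel") <- fv$submodel
  D
}

pair_euclidean <- function(P, C) {
  D <- matrix(0, nrow(P), nrow(C))
  tC <- t(C)
  for (i in seq_len(nrow(P)))
    D[i, ] <- sqrt(colSums((tC - P[i, ])^2))
  D
}

pair_spearman <- function(P, C) {
  if (ncol(P) < 2L) stop("spearman metric needs vectors of width >= 2")
  rp <- row_rank_centered(P)
  rc <- row_rank_centered(C)
  np <- sqrt(rowSums(rp^2)); nc <- sqrt(rowSums(rc^2))
  S <- tcrossprod(rp, rc) / outer(np, nc)
  S[!is.finite(S)] <- 0        # constant vectors: correlation undefined, score 0
  pmin(pmax(S, -1), 1)
}

row_rank_centered <- function(X) {
  R <- t(apply(X, 1L, rank))
  R - (ncol(X) + 1) / 2
}

#' Identify dyads from a CBI distance matrix
#'
#' Applies the sub-model's extremum rule per parent (row): positive features
#' pair a parent with the child at minimum Euclidean distance / maximum
#' Spearman correlation; negative features with the child at maximum distance
#' / minimum correlation. A dyad is identified (score one) when the extremum
#' falls on the diagonal. Ties go to the lowest column index with a warning.
#'
#' @param values n-by-n numeric matrix (rows = parents, columns = children).
#' @param submodel `"positive"` or `"negative"`; defaults to the matrix's
#'   `submodel` attribute when present.
#' @param metric `"euclidean"` or `"spearman"`; defaults likewise.
#' @return List with `matches`, logical `hits`, `rate`, and the applied `rule`.
#' @export
cbi_identify <- function(values, submodel = NULL, metric = NULL) {
  submodel <- match.arg(submodel %||% attr(values, "submodel"),
                        c("positive", "negative"))
  metric <- match.arg(metric %||% attr(values, "metric"),
                      c("euclidean", "spearman"))
  rule <- cbi_rule(submodel, metric)
  out <- identify_rows(values, rule)
  out$submodel <- submodel
  out$metric <- metric
  out
}

cbi_rule <- function(submodel, metric) {
  if (submodel == "positive") {
    if (metric == "euclidean") "min" else "max"
  } else {
    if (metric == "euclidean") "max" else "min"
  }
}

#' Fit the connectome-based identification (CBI) model
#'
#' Runs the full CBI procedure on a dyad cohort: cross-group edgewise
#' Spearman feature selection ([edgewise_spearman()]), feature-vector
#' representation of every subject ([feature_vectors()]), the four
#' parents-by-children distance matrices (positive/negative sub-model by
#' Euclidean/Spearman metric, [cbi_distance()]), and the extremum-rule
#' identification of dyads on each ([cbi_identify()]).
#'
#' @param cohort An [fc_cohort()].
#' @param alpha Edgewise significance threshold (default 0.05).
#' @param p_method Passed to [edgewise_spearman()].
#' @return Object of class `"cbi"`: list with `features`, per-sub-model
#'   entries holding `vectors` plus per-metric `values` (the distance matrix)
#'   and `id` (identification result), and a `rates` data frame. Sub-models
#'   whose mask is empty are dropped and listed in `$unavailable`.
#' @examples
#' co <- simulate_cohort(n_dyads = 8, n_roi = 20, coupling = 1.5,
#'                       noise_sd = 0.1, seed = 3)
#' fit <- cbi(co)
#' summary(fit)
#' @export
cbi <- function(cohort, alpha = 0.05, p_method = "t-approximation") {
  stopifnot(inherits(cohort, "fc_cohort"))
  features <- edgewise_spearman(cohort, alpha = alpha, p_method = p_method)
  fit <- list(features = features, n_dyads = cohort$n_dyads,
              dyad_ids = cohort$dyad_ids, alpha = alpha,
              unavailable = character(0), call = match.call())
  rates <- list()
  for (sm in c("positive", "negative")) {
    mask <- if (sm == "positive") features$pos else features$neg
    if (!any(mask)) {
      fit$unavailable <- c(fit$unavailable, sm)
      next
    }
    fv <- feature_vectors(cohort, features, sm)
    entry <- list(vectors = fv)
    for (met in c("euclidean", "spearman")) {
      D <- cbi_distance(fv, met)
      id <- cbi_identify(D, sm, met)
      entry[[met]] <- list(values = D, id = id)
      rates[[length(rates) + 1L]] <- data.frame(
        submodel = sm, metric = met, n_features = length(fv$edges),
        identified = sum(id$hits), n_dyads = cohort$n_dyads, rate = id$rate)
    }
    fit[[sm]] <- entry
  }
  fit$rates <- if (length(rates)) do.call(rbind, rates) else NULL
  class(fit) <- "cbi"
  fit
}

#' @export
print.cbi <- function(x, ...) {
  cat("Connectome-based identification (CBI) model, ",
      x$n_dyads, " dyads\n", sep = "")
  print(x$features)
  if (!is.null(x$rates)) {
    for (k in seq_len(nrow(x$rates))) {
      row <- x$rates[k, ]
      cat(sprintf("  %-8s %-9s : %d/%d identified (%.1f%%)\n",
                  row$submodel, row$metric, row$identified, row$n_dyads,
                  100 * row$rate))
    }
  }
  if (length(x$unavailable))
    cat("  unavailable sub-model(s): ", paste(x$unavailable, collapse = ", "),
        " (empty feature mask)\n", sep = "")
  invisible(x)
}

#' @export
summary.cbi <- function(object, ...) {
  structure(list(fit = object), class = "summary.cbi")
}

#' @export
print.summary.cbi <- function(x, ...) {
  print(x$fit)
  f <- x$fit$features
  cat("Selected-edge fraction: ",
      sprintf("%.4f", (sum(f$pos) + sum(f$neg)) / length(f$rho)),
      " of ", length(f$rho), " edges\n", sep = "")
  invisible(x)
}

#' Selected features of a CBI fit
#'
#' @param object A `"cbi"` fit.
#' @param ... Unused.
#' @return Data frame with one row per selected edge: ROI indices `i`, `j`,
#'   `rho`, `p` and `sign` (`"positive"`/`"negative"`).
#' @export
coef.cbi <- function(object, ...) {
  f <- object$features
  idx <- edge_index(f$n_roi)
  sel <- which(f$pos | f$neg)
  data.frame(i = idx$i[sel], j = idx$j[sel],
             rho = f$rho[sel], p = f$p[sel],
             sign = ifelse(f$pos[sel], "positive", "negative"))
}

#' Heatmap of a CBI distance matrix
#'
#' @param x A `"cbi"` fit.
#' @param submodel,metric Which distance matrix to draw.
#' @param ... Passed to [graphics::image()].
#' @export
plot.cbi <- function(x, submodel = c("positive", "negative"),
                     metric = c("euclidean", "spearman"), ...) {
  submodel <- match.arg(submodel)
  metric <- match.arg(metric)
  if (is.null(x[[submodel]])) stop("sub-model ", submodel, " unavailable in this fit")
  D <- x[[submodel]][[metric]]$values
  n <- nrow(D)
  graphics::image(seq_len(n), seq_len(n), t(D[n:1, , drop = FALSE]),
                  xlab = "children", ylab = "parents", axes = FALSE,
                  main = paste(submodel, "sub-model,", metric), ...)
  graphics::axis(1, at = seq_len(n)); graphics::axis(2, at = seq_len(n), labels = n:1)
  graphics::points(seq_len(n), n:1, pch = 0, cex = 2)
  invisible(x)
}
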