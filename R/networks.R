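#' Count selected features per network-to-network node
#'
#' A "node" is the block of edges joining two named functional networks
#' (diagonal nodes are within-network blocks). Each selected edge \eqn{(i,j)}
#' increments the node `(network(i), network(j))` once; because the feature
#' masks live on the deduplicated strict upper triangle, symmetric duplicates
#' are never double counted. Counts are reported as a symmetric matrix.
#'
#' @param mask Logical per-edge vector of length \eqn{r(r-1)/2} in
#'   [edge_index()] order.
#' @param labels Character/factor vector of length `r` mapping ROIs to
#'   networks; no missing values allowed.
#' @return Symmetric K-by-K integer matrix with network names as dimnames,
#'   networks ordered by first appearance in `labels`.
#' @export
count_node_features <- function(mask, labels) {
  labels <- as.character(labels)
  if (anyNA(labels)) stop("unlabeled ROI: every ROI needs a network label")
  r <- length(labels)
  if (length(mask) != r * (r - 1L) / 2L)
    stop("mask length ", length(mask), " does not match ", r, " ROIs")
  nets <- unique(labels)
  K <- length(nets)
  counts <- matrix(0L, K, K, dimnames = list(nets, nets))
  if (any(mask)) {
    idx <- edge_index(r)
    a <- match(labels[idx$i[mask]], nets)
    b <- match(labels[idx$j[mask]], nets)
    lo <- pmin(a, b); hi <- pmax(a, b)
    tab <- table(factor(lo, levels = seq_len(K)), factor(hi, levels = seq_len(K)))
    upper <- matrix(as.integer(tab), K, K)
    counts <- upper + t(upper)
    diag(counts) <- diag(upper)
    dimnames(counts) <- list(nets, nets)
  }
  counts
}

#' Normalize node counts by the sub-model's total feature count
#'
#' Divides each node count by the total number of selected features of the
#' sub-model, so the unique nodes (upper triangle plus diagonal) sum to 1:
#' the portion of the identifying features each node contributed.
#'
#' @param counts Symmetric count matrix from [count_node_features()].
#' @return Symmetric K-by-K matrix of fractions (all zero, with a warning,
#'   when no feature is selected).
#' @export
normalize_by_total <- function(counts) {
  total <- sum(counts[upper.tri(counts, diag = TRUE)])
  if (total == 0) {
    warning("no selected features; fractions are all zero")
    return(counts * 0)
  }
  counts / total
}

#' Normalize node counts by node size
#'
#' Divides each node's count by the number of distinct edges the node
#' contains: \eqn{n_A n_B} for an off-diagonal node joining networks of sizes
#' \eqn{n_A, n_B}, and \eqn{n_A(n_A-1)/2} for a within-network node
#' (self-connections are constant 1 in an FC profile and can never be
#' selected, so they are excluded from node sizes). Values lie in
#' \eqn{[0, 1]}: the "relative contribution" of the node.
#'
#' @param counts Symmetric count matrix from [count_node_features()].
#' @param labels The ROI-to-network labels the counts were built with.
#' @return Symmetric K-by-K matrix; a single-ROI network's diagonal node has
#'   size 0 and is reported as 0 with a warning.
#' @export
normalize_by_node_size <- function(counts, labels) {
  labels <- as.character(labels)
  nets <- rownames(counts)
  sizes <- as.numeric(table(factor(labels, levels = nets)))
  denom <- outer(sizes, sizes)
  diag(denom) <- sizes * (sizes - 1) / 2
  if (any(diag(denom) == 0))
    warning("network(s) of size 1 have no within-network edges; reported as 0")
  out <- ifelse(denom > 0, counts / denom, 0)
  dimnames(out) <- dimnames(counts)
  out
}

#' Network-to-network contribution of a CBI sub-model's features
#'
#' Bundles the three accounting matrices for one sub-model: raw counts,
#' fraction of the sub-model's total features, and the size-normalized
#' relative contribution.
#'
#' @param features A [edgewise_spearman()] selection (or a [cbi()] fit,
#'   whose `$features` is used).
#' @param labels ROI-to-network labels (defaults to the cohort labels stored
#'   in neither object, so usually passed explicitly).
#' @param submodel `"positive"` or `"negative"`.
#' @return Object of class `"node_contribution"`: list with `counts`,
#'   `fraction_of_total`, `per_size`, `submodel`, `n_features`.
#' @export
network_contribution <- function(features, labels,
                                 submodel = c("positive", "negative")) {
  if (inherits(features, "cbi")) features <- features$features
  stopifnot(inherits(features, "cbi_features"))
  submodel <- match.arg(submodel)
  mask <- if (submodel == "positive") features$pos else features$neg
  counts <- count_node_features(mask, labels)
  structure(
    list(counts = counts,
         fraction_of_total = normalize_by_total(counts),
         per_size = normalize_by_node_size(counts, labels),
         submodel = submodel, n_features = sum(mask)),
    class = "node_contribution")
}

#' @export
print.node_contribution <- function(x, digits = 3, ...) {
  cat("Network-to-network contribution, ", x$submodel, " sub-model (",
      x$n_features, " features)\n", sep = "")
  ut <- upper.tri(x$counts, diag = TRUE)
  ord <- order(x$counts[ut], decreasing = TRUE)
  pairs <- which(ut, arr.ind = TRUE)[ord, , drop = FALSE]
  top <- utils::head(pairs[x$counts[pairs] > 0, , drop = FALSE], 5L)
  if (nrow(top)) {
    cat("  top nodes (count | fraction | per-size):\n")
    for (k in seq_len(nrow(top))) {
      i <- top[k, 1L]; j <- top[k, 2L]
      cat(sprintf("    %s-%s: %d | %.3f | %.3f\n",
                  rownames(x$counts)[i], colnames(x$counts)[j],
                  x$counts[i, j], x$fraction_of_total[i, j], x$per_size[i, j]))
    }
  } else cat("  (no features selected)\n")
  invisible(x)
}
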