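#' Affine-invariant Riemannian distance between SPD matrices
#'
#' \eqn{d(A, B) = \|\log(A^{-1/2} B A^{-1/2})\|_F
#'   = \sqrt{\sum_k \log^2 \lambda_k}}, where \eqn{\lambda_k} are the
#' generalized eigenvalues of \eqn{(A, B)}. Invariant under congruence
#' \eqn{(A, B) \to (MAM^\top, MBM^\top)} for any invertible \eqn{M}.
#'
#' @param a,b Symmetric positive-definite matrices of equal dimension.
#' @return Non-negative scalar.
#' @export
riemannian_distance <- function(a, b) {
  ea <- eigen(a, symmetric = TRUE)
  if (min(ea$values) <= 0) stop("not_positive_definite: first argument")
  ihalf <- ea$vectors %*% (t(ea$vectors) / sqrt(ea$values))
  s <- ihalf %*% b %*% t(ihalf)
  ev <- eigen((s + t(s)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("not_positive_definite: second argument")
  sqrt(sum(log(ev)^2))
}

#' Log-Euclidean distance between SPD matrices
#'
#' \eqn{d(A, B) = \|\log A - \log B\|_F}; a cheaper alternative to the
#' affine-invariant metric that agrees with it for commuting matrices.
#'
#' @inheritParams riemannian_distance
#' @return Non-negative scalar.
#' @export
log_euclidean_distance <- function(a, b) {
  sqrt(sum((spd_log(a) - spd_log(b))^2))
}

spd_log <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(e$values) <= 0) stop("not_positive_definite: matrix log undefined")
  e$vectors %*% (log(e$values) * t(e$vectors))
}

#' Pairwise distance matrix over a set of profiles
#'
#' @param profiles Either a numeric matrix (rows = profiles, Euclidean metric
#'   only) or a list of square symmetric matrices (any metric; each is passed
#'   through [ensure_spd()] first for the SPD metrics).
#' @param metric `"euclidean"`, `"riemannian"` (affine-invariant) or
#'   `"log-euclidean"`. For matrix-valued profiles the Euclidean metric is
#'   the Frobenius distance.
#' @param shrinkage Ridge passed to [ensure_spd()] for the SPD metrics
#'   (default 0: inputs must already be positive definite).
#' @return Symmetric N-by-N matrix with zero diagonal.
#' @export
pairwise_distances <- function(profiles,
                               metric = c("euclidean", "riemannian", "log-euclidean"),
                               shrinkage = 0) {
  metric <- match.arg(metric)
  if (is.matrix(profiles) && is.numeric(profiles)) {
    if (metric != "euclidean")
      stop("vector-valued profiles support the euclidean metric only")
    return(as.matrix(stats::dist(profiles)))
  }
  if (!is.list(profiles)) stop("profiles must be a numeric matrix or a list of matrices")
  n <- length(profiles)
  if (n < 3L) stop("need at least 3 profiles")
  if (metric == "euclidean") {
    flat <- t(vapply(profiles, as.vector, numeric(length(profiles[[1L]]))))
    return(as.matrix(stats::dist(flat)))
  }
  spd <- lapply(profiles, ensure_spd, shrinkage = shrinkage)
  D <- matrix(0, n, n)
  fun <- if (metric == "riemannian") riemannian_distance else log_euclidean_distance
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- fun(spd[[i]], spd[[j]])
  }
  D
}

#' Kernel scale heuristic
#'
#' \eqn{\varepsilon} = `scale` times the median squared off-diagonal
#' distance. Any positive scale keeps the Gaussian kernel strictly positive
#' (all nodes connected); the median heuristic makes the default scale-free.
#'
#' @param distances Symmetric distance matrix.
#' @param scale Multiplier (default 1).
#' @return Positive scalar.
#' @export
select_epsilon <- function(distances, scale = 1) {
  d2 <- distances[upper.tri(distances)]^2
  if (!any(d2 > 0)) stop("all off-diagonal distances are zero")
  scale * stats::median(d2)
}

#' Gaussian affinity kernel
#'
#' \eqn{K(i, j) = \exp(-d(i, j)^2 / \varepsilon)}: symmetric, entries in
#' \eqn{(0, 1]}, unit diagonal for zero self-distance.
#'
#' @param distances Symmetric distance matrix.
#' @param epsilon Kernel scale, > 0.
#' @return Kernel matrix of the same dimension.
#' @export
gaussian_kernel <- function(distances, epsilon) {
  if (length(epsilon) != 1L || !is.finite(epsilon) || epsilon <= 0)
    stop("epsilon must be a single positive number")
  exp(-distances^2 / epsilon)
}

#' Row-normalize a kernel into a Markov transition matrix
#'
#' \eqn{P(i, j) = K(i, j) / d(i)} with degree \eqn{d(i) = \sum_j K(i, j)}:
#' the probability that a random walker steps from profile \eqn{i} to
#' \eqn{j}. The degree vector is kept as attribute `degree` so the
#' eigendecomposition can use the symmetric conjugate.
#'
#' @param kernel Symmetric kernel with strictly positive row sums.
#' @return Row-stochastic matrix with attribute `degree`.
#' @export
markov_normalize <- function(kernel) {
  d <- rowSums(kernel)
  if (any(d <= 0)) stop("kernel has a non-positive row sum")
  P <- kernel / d
  attr(P, "degree") <- d
  P
}

#' Diffusion-map coordinates from a transition matrix
#'
#' Eigendecomposes \eqn{P} through its symmetric conjugate
#' \eqn{D^{-1/2} K D^{-1/2}} for numerical stability. The trivial eigenpair
#' (eigenvalue exactly 1, constant right eigenvector) is discarded;
#' coordinate \eqn{k} of profile \eqn{i} is \eqn{\lambda_k \phi_k(i)} for the
#' next `l` pairs, with eigenvectors unit-normalized and signs fixed so each
#' vector's first maximal-magnitude component is positive.
#'
#' @param P Row-stochastic matrix from [markov_normalize()] (the `degree`
#'   attribute is required).
#' @param l Embedding dimension (default 2); must be < N.
#' @return List with `coordinates` (N-by-l), `eigenvalues` (descending,
#'   trivial pair excluded) and `trivial_eigenvalue` (numerically 1).
#' @export
diffusion_coords <- function(P, l = 2) {
  d <- attr(P, "degree")
  if (is.null(d)) stop("P must come from markov_normalize() (degree attribute missing)")
  N <- nrow(P)
  if (l > N - 1L) stop("l must be at most N - 1")
  K <- P * d                       # recover the symmetric kernel
  s <- 1 / sqrt(d)
  A <- K * outer(s, s)
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lambda <- e$values               # descending
  phi <- s * e$vectors             # right eigenvectors of P
  phi <- sweep(phi, 2L, sqrt(colSums(phi^2)), "/")
  for (k in seq_len(ncol(phi))) {
    imax <- which.max(abs(phi[, k]))
    if (phi[imax, k] < 0) phi[, k] <- -phi[, k]
  }
  coords <- phi[, 1L + seq_len(l), drop = FALSE] *
    rep(lambda[1L + seq_len(l)], each = N)
  list(coordinates = coords, eigenvalues = lambda[-1L],
       trivial_eigenvalue = lambda[1L])
}

#' Diffusion-map embedding of connectivity or feature profiles
#'
#' Full pipeline: pairwise distances, Gaussian kernel at a median-heuristic
#' scale, Markov normalization, and spectral embedding. Whole-brain FC
#' profiles (SPD after shrinkage) admit the affine-invariant Riemannian
#' metric; feature-vector profiles use the Euclidean metric.
#'
#' @param profiles Numeric matrix (rows = profiles) or list of symmetric
#'   matrices; see [pairwise_distances()].
#' @param metric Distance metric (see [pairwise_distances()]).
#' @param epsilon_scale Multiplier for the median-heuristic kernel scale.
#' @param l Embedding dimension (default 2).
#' @param shrinkage Ridge for SPD metrics (default 0).
#' @param roles,dyads,ids Optional per-profile annotations (role
#'   `"parent"`/`"child"`, dyad id, subject id) carried into the result and
#'   used by [dyad_distance_stats()] and the plot method.
#' @return Object of class `"diffusion_map"`: list with `coordinates`,
#'   `eigenvalues`, `trivial_eigenvalue`, `epsilon`, `metric`, `distances`,
#'   and the annotations.
#' @examples
#' co <- simulate_cohort(n_dyads = 6, n_roi = 16, coupling = 1.5,
#'                       noise_sd = 0.1, seed = 5)
#' fit <- cbi(co)
#' dm <- diffusion_map(rbind(fit$positive$vectors$parents,
#'                           fit$positive$vectors$children),
#'                     roles = rep(c("parent", "child"), each = 6),
#'                     dyads = rep(co$dyad_ids, 2))
#' @export
diffusion_map <- function(profiles,
                          metric = c("euclidean", "riemannian", "log-euclidean"),
                          epsilon_scale = 1, l = 2, shrinkage = 0,
                          roles = NULL, dyads = NULL, ids = NULL) {
  metric <- match.arg(metric)
  D <- pairwise_distances(profiles, metric, shrinkage = shrinkage)
  eps <- select_epsilon(D, scale = epsilon_scale)
  P <- markov_normalize(gaussian_kernel(D, eps))
  emb <- diffusion_coords(P, l = l)
  structure(
    c(emb, list(epsilon = eps, metric = metric, distances = D,
                roles = roles, dyads = dyads, ids = ids)),
    class = "diffusion_map")
}

#' @export
print.diffusion_map <- function(x, ...) {
  cat("Diffusion map: ", nrow(x$coordinates), " profiles, ",
      ncol(x$coordinates), "D embedding, ", x$metric, " metric\n", sep = "")
  cat(sprintf("  epsilon = %.4g; leading eigenvalues: %s\n", x$epsilon,
              paste(sprintf("%.3f", utils::head(x$eigenvalues, 4L)),
                    collapse = ", ")))
  invisible(x)
}

#' Scatter plot of a diffusion-map embedding
#'
#' Dyads share a color; parents are filled circles, children open triangles.
#'
#' @param x A `"diffusion_map"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.diffusion_map <- function(x, ...) {
  co <- x$coordinates
  cols <- if (!is.null(x$dyads)) {
    pal <- grDevices::hcl.colors(length(unique(x$dyads)), "Dark 3")
    pal[match(x$dyads, unique(x$dyads))]
  } else "black"
  pch <- if (!is.null(x$roles)) ifelse(x$roles == "parent", 19, 2) else 19
  graphics::plot(co[, 1L], co[, 2L], col = cols, pch = pch,
                 xlab = expression(lambda[1] * phi[1]),
                 ylab = expression(lambda[2] * phi[2]),
                 main = paste("Diffusion map (", x$metric, ")", sep = ""), ...)
  invisible(x)
}

#' Biological vs unrelated dyad distances in an embedding
#'
#' Compares the embedded Euclidean distances of the \eqn{n} biological
#' parent-child couples with the \eqn{n^2 - n} unrelated parent-child
#' cross-pairings: means, standard errors (sd/sqrt(m)), and a two-sided
#' Mann-Whitney rank-sum test (normal approximation with tie correction).
#' The unrelated pairings share subjects and are not independent; the test
#' treats them as observations all the same, matching the procedure it
#' mirrors.
#'
#' @param emb A `"diffusion_map"` with `roles` and `dyads` set, or a numeric
#'   coordinate matrix.
#' @param roles,dyads Required when `emb` is a bare matrix.
#' @return Object of class `"dyad_stats"`: list with `mean_bio`, `se_bio`,
#'   `mean_unrel`, `se_unrel`, `u_statistic`, `p_value`, `n_dyads`.
#' @export
dyad_distance_stats <- function(emb, roles = NULL, dyads = NULL) {
  if (inherits(emb, "diffusion_map")) {
    roles <- roles %||% emb$roles
    dyads <- dyads %||% emb$dyads
    co <- emb$coordinates
  } else co <- as.matrix(emb)
  if (is.null(roles) || is.null(dyads)) stop("roles and dyads are required")
  pidx <- which(roles == "parent")
  cidx <- which(roles == "child")
  n <- length(pidx)
  if (n < 2L || length(cidx) != n) stop("need n >= 2 parents matched by n children")
  cidx <- cidx[match(dyads[pidx], dyads[cidx])]  # align children to parent order
  if (anyNA(cidx)) stop("every parent dyad needs a matching child")
  D <- as.matrix(stats::dist(co))[pidx, cidx, drop = FALSE]
  bio <- diag(D)
  unrel <- D[row(D) != col(D)]
  wt <- stats::wilcox.test(bio, unrel, exact = FALSE, correct = FALSE)
  structure(
    list(mean_bio = mean(bio), se_bio = stats::sd(bio) / sqrt(length(bio)),
         mean_unrel = mean(unrel),
         se_unrel = stats::sd(unrel) / sqrt(length(unrel)),
         u_statistic = unname(wt$statistic), p_value = wt$p.value,
         n_dyads = n),
    class = "dyad_stats")
}

#' @export
print.dyad_stats <- function(x, ...) {
  cat("Embedded parent-child distances (", x$n_dyads, " dyads)\n", sep = "")
  cat(sprintf("  biological: %.4f (SE %.4f); unrelated: %.4f (SE %.4f)\n",
              x$mean_bio, x$se_bio, x$mean_unrel, x$se_unrel))
  cat(sprintf("  Mann-Whitney U = %.1f, two-sided p = %.4g\n",
              x$u_statistic, x$p_value))
  invisible(x)
}
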