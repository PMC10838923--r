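#' Compute a functional connectivity (FC) profile from ROI time series
#'
#' An FC profile is the symmetric \eqn{r \times r} matrix of sample Pearson
#' correlations between the time series of \eqn{r} regions of interest (ROIs).
#' Row \eqn{t} of `ts` is one time point, column \eqn{j} one ROI.
#'
#' @param ts Numeric matrix, time points by ROIs. At least 3 rows and 2
#'   columns; all entries finite; every column must have nonzero variance.
#' @param subject_id Optional subject identifier stored as an attribute.
#' @param fisher Logical; apply the Fisher z-transform (`atanh`) to the
#'   off-diagonal entries. Off by default: downstream identification is
#'   rank- or correlation-based and unaffected by monotone transforms.
#' @return An \eqn{r \times r} numeric matrix with unit diagonal, symmetric,
#'   entries in \eqn{[-1, 1]} (unbounded off-diagonals when `fisher = TRUE`),
#'   with attribute `subject_id`.
#' @seealso [vectorize_upper()], [validate_fc_profile()]
#' @examples
#' ts <- matrix(rnorm(150 * 10), 150, 10)
#' fc <- fc_profile(ts, subject_id = "s1")
#' @export
fc_profile <- function(ts, subject_id = NULL, fisher = FALSE) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stop("time series must be numeric")
  if (nrow(ts) < 3L) stop("need at least 3 time points, got ", nrow(ts))
  if (ncol(ts) < 2L) stop("need at least 2 ROIs, got ", ncol(ts))
  if (!all(is.finite(ts))) stop("time series contains non-finite values")
  v <- apply(ts, 2L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    stop("zero_variance_column: ROI column(s) ",
         paste(bad, collapse = ", "), " have zero variance")
  }
  m <- stats::cor(ts)
  m <- (m + t(m)) / 2           # enforce exact symmetry
  diag(m) <- 1
  m[m > 1] <- 1
  m[m < -1] <- -1
  if (fisher) {
    off <- row(m) != col(m)
    m[off] <- atanh(m[off])
  }
  dimnames(m) <- NULL
  attr(m, "subject_id") <- subject_id
  m
}

#' Validate an FC profile matrix
#'
#' Checks symmetry (to `tol`), unit diagonal and range \eqn{[-1, 1]}.
#'
#' @param m Square numeric matrix.
#' @param tol Absolute tolerance for the symmetry and diagonal checks.
#' @return `m`, invisibly; errors with an informative message otherwise.
#' @export
validate_fc_profile <- function(m, tol = 1e-12) {
  if (!is.matrix(m) || !is.numeric(m)) stop("FC profile must be a numeric matrix")
  if (nrow(m) != ncol(m)) stop("FC profile must be square")
  if (!all(is.finite(m))) stop("FC profile contains non-finite values")
  if (max(abs(m - t(m))) > tol) stop("FC profile is not symmetric (tol ", tol, ")")
  if (max(abs(diag(m) - 1)) > tol) stop("FC profile diagonal is not 1 (tol ", tol, ")")
  if (any(m > 1 + tol) || any(m < -1 - tol)) stop("FC profile entries outside [-1, 1]")
  invisible(m)
}

#' Canonical edge index of the strict upper triangle
#'
#' Enumerates the \eqn{r(r-1)/2} unordered ROI pairs \eqn{(i, j)}, \eqn{i < j},
#' in row-major order: (1,2), (1,3), ..., (1,r), (2,3), ... This is the column
#' order of every edge vector in the package ("edge" and "feature" are used
#' interchangeably for a single ROI-to-ROI connection).
#'
#' @param r ROI count (>= 2).
#' @return Data frame with integer columns `i`, `j` (1-based ROI indices).
#' @export
edge_index <- function(r) {
  r <- as.integer(r)
  if (r < 2L) stop("r must be >= 2")
  i <- rep.int(seq_len(r - 1L), times = (r - 1L):1L)
  j <- unlist(lapply(seq_len(r - 1L), function(k) (k + 1L):r), use.names = FALSE)
  data.frame(i = i, j = j)
}

#' Vectorize the strict upper triangle of a symmetric matrix
#'
#' Returns the off-diagonal edge values in [edge_index()] order (row-major,
#' diagonal excluded). The constant unit diagonal of an FC profile carries no
#' information and symmetric duplicates are dropped, so this vector is the
#' deduplicated representation used throughout.
#'
#' @param m Square numeric matrix.
#' @return Numeric vector of length \eqn{r(r-1)/2}.
#' @seealso [devectorize_upper()] for the exact inverse.
#' @export
vectorize_upper <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("need a square matrix")
  t(m)[lower.tri(m)]
}

#' Rebuild a symmetric matrix from its upper-triangle edge vector
#'
#' Exact inverse of [vectorize_upper()] on the off-diagonal entries.
#'
#' @param v Edge vector of length \eqn{r(r-1)/2} in [edge_index()] order.
#' @param r ROI count.
#' @param diag Value placed on the diagonal (default 1, the FC convention).
#' @return Symmetric \eqn{r \times r} matrix.
#' @export
devectorize_upper <- function(v, r, diag = 1) {
  r <- as.integer(r)
  if (length(v) != r * (r - 1L) / 2L)
    stop("edge vector length ", length(v), " does not match r = ", r,
         " (expected ", r * (r - 1L) / 2L, ")")
  m <- matrix(0, r, r)
  m[lower.tri(m)] <- v          # fills column-major = row-major of the transpose
  m <- t(m)
  m <- m + t(m)
  diag(m) <- diag
  m
}

#' Shrink an FC profile towards the identity to make it positive definite
#'
#' Returns \eqn{(1-\gamma) M + \gamma I}. Correlation matrices estimated from
#' fewer time points than ROIs are rank deficient; the affine-invariant
#' Riemannian distance needs strictly positive eigenvalues, so a small ridge
#' \eqn{\gamma} is applied first. The minimum eigenvalue of the result is
#' \eqn{(1-\gamma)\lambda_{\min}(M) + \gamma \ge \gamma} whenever
#' \eqn{\lambda_{\min}(M) \ge 0}.
#'
#' @param m Symmetric matrix (typically an FC profile).
#' @param shrinkage Ridge weight \eqn{\gamma \in [0, 1]}.
#' @param tol Eigenvalue tolerance below which `m` counts as singular.
#' @return Symmetric positive-definite matrix of the same dimension.
#' @export
ensure_spd <- function(m, shrinkage, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("need a square matrix")
  if (length(shrinkage) != 1L || is.na(shrinkage) || shrinkage < 0 || shrinkage > 1)
    stop("shrinkage must be a single value in [0, 1]")
  m <- (m + t(m)) / 2
  if (shrinkage == 0) {
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= tol)
      stop("not_positive_definite: matrix is singular (min eigenvalue ",
           format(min(ev)), ") and shrinkage is 0")
    return(m)
  }
  out <- (1 - shrinkage) * m
  diag(out) <- diag(out) + shrinkage
  out
}
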