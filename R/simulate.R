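#' Simulate a dyad cohort with planted cross-dyad edge coupling
#'
#' Generates index-aligned parent and child sets of FC profiles in which a
#' chosen subset of edges is positively coupled across dyads, a disjoint
#' subset negatively coupled, and every other edge carries independent noise.
#' Defaults mirror the reference study design: 13 dyads, 264 ROIs, 150 time
#' points.
#'
#' For each edge \eqn{e} a baseline \eqn{\mu_e} is drawn once per cohort from
#' Normal(0.1, 0.2^2) truncated to (-0.8, 0.8). For dyad \eqn{d}, with latent
#' \eqn{u_{d,e} \sim N(0,1)} per edge, the edge values before squashing are
#' \deqn{parent: \mu_e + c\, u_{d,e} + a\, g_{d,e} + \sigma \epsilon}
#' \deqn{child:  \mu_e + s_e c\, u_{d,e} + a\, g_{d,e} + \sigma \epsilon'}
#' with \eqn{s_e = +1} on planted positive edges, \eqn{-1} on planted negative
#' edges and 0 elsewhere, \eqn{c} = `coupling`, \eqn{\sigma} = `noise_sd`, and
#' \eqn{a} = `individual_strength` scaling a dyad-specific whole-connectome
#' component \eqn{g_{d,e}} shared by both members (the "fingerprint" signal a
#' whole-brain matcher can exploit). Values are squashed by `tanh` so the
#' profiles stay valid correlation matrices without clipping artifacts.
#'
#' In `mode = "timeseries"` the same edge construction defines a per-subject
#' target correlation matrix, which is floored to positive definiteness
#' (eigenvalue floor, then rescaled to unit diagonal) and used to draw a
#' `n_time` by `n_roi` Gaussian series; [fc_profile()] then gives the profile,
#' so the planted structure is additionally blurred by sampling error.
#'
#' @param n_dyads Number of parent-child couples (>= 2; default 13).
#' @param n_roi ROI count (default 264).
#' @param n_time Time points for `mode = "timeseries"` (default 150).
#' @param pos_edges,neg_edges Integer vectors of edge positions in
#'   [edge_index()] order for the planted positively / negatively coupled
#'   sets; must be disjoint and in range. When `NULL`, random disjoint sets
#'   of sizes `round(prop_pos * E)` and `round(prop_neg * E)` are drawn.
#' @param prop_pos,prop_neg Planted fractions used when the edge sets are not
#'   given explicitly (defaults 0.05 each).
#' @param coupling Cross-dyad shared-signal strength \eqn{c \ge 0} (default 1).
#' @param noise_sd Edge noise standard deviation \eqn{\sigma > 0} (default 0.3).
#' @param individual_strength Dyad-shared whole-connectome component scale
#'   \eqn{a \ge 0} (default 0: whole-brain fingerprinting stays at chance).
#' @param mode `"fc-direct"` (default) draws edge values directly;
#'   `"timeseries"` draws time series and correlates them.
#' @param seed Integer seed; the same seed reproduces the cohort bit for bit.
#' @param network_labels Optional ROI network labels to attach; `TRUE`
#'   attaches the bundled 14-network synthetic labeling via
#'   [synthetic_network_labels()].
#' @return An [fc_cohort()] with attributes `planted_pos`, `planted_neg`
#'   (the planted edge positions) and `config`.
#' @examples
#' co <- simulate_cohort(n_dyads = 6, n_roi = 20, coupling = 1.5,
#'                       noise_sd = 0.1, seed = 7)
#' @export
simulate_cohort <- function(n_dyads = 13, n_roi = 264, n_time = 150,
                            pos_edges = NULL, neg_edges = NULL,
                            prop_pos = 0.05, prop_neg = 0.05,
                            coupling = 1, noise_sd = 0.3,
                            individual_strength = 0,
                            mode = c("fc-direct", "timeseries"),
                            seed = NULL, network_labels = NULL) {
  mode <- match.arg(mode)
  if (n_dyads < 2) stop("n_dyads must be >= 2")
  if (coupling < 0) stop("coupling must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (individual_strength < 0) stop("individual_strength must be >= 0")
  r <- as.integer(n_roi)
  E <- (r * (r - 1L)) %/% 2L
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (is.null(pos_edges) && is.null(neg_edges)) {
    n_pos <- round(prop_pos * E)
    n_neg <- round(prop_neg * E)
    pick <- sample.int(E, n_pos + n_neg)
    pos_edges <- pick[seq_len(n_pos)]
    neg_edges <- pick[n_pos + seq_len(n_neg)]
  }
  pos_edges <- as.integer(pos_edges %||% integer(0))
  neg_edges <- as.integer(neg_edges %||% integer(0))
  if (length(intersect(pos_edges, neg_edges)))
    stop("planted positive and negative edge sets must be disjoint")
  if (any(c(pos_edges, neg_edges) < 1L) || any(c(pos_edges, neg_edges) > E))
    stop("planted edge positions must lie in 1..", E)

  s <- numeric(E)
  s[pos_edges] <- 1
  s[neg_edges] <- -1

  # per-cohort edge baselines, truncated normal
  mu <- stats::rnorm(E, 0.1, 0.2)
  while (any(bad <- abs(mu) >= 0.8)) mu[bad] <- stats::rnorm(sum(bad), 0.1, 0.2)

  parents <- children <- vector("list", n_dyads)
  for (d in seq_len(n_dyads)) {
    u <- stats::rnorm(E)
    g <- stats::rnorm(E)
    zp <- mu + coupling * u + individual_strength * g + noise_sd * stats::rnorm(E)
    zc <- mu + s * coupling * u + individual_strength * g + noise_sd * stats::rnorm(E)
    if (mode == "fc-direct") {
      parents[[d]] <- devectorize_upper(tanh(zp), r)
      children[[d]] <- devectorize_upper(tanh(zc), r)
    } else {
      parents[[d]] <- sample_fc_from_target(tanh(zp), r, n_time)
      children[[d]] <- sample_fc_from_target(tanh(zc), r, n_time)
    }
  }

  if (isTRUE(network_labels)) network_labels <- synthetic_network_labels(r)
  co <- fc_cohort(parents, children, network_labels = network_labels)
  attr(co, "planted_pos") <- sort(pos_edges)
  attr(co, "planted_neg") <- sort(neg_edges)
  attr(co, "config") <- list(
    n_dyads = n_dyads, n_roi = r, n_time = n_time, prop_pos = prop_pos,
    prop_neg = prop_neg, coupling = coupling, noise_sd = noise_sd,
    individual_strength = individual_strength, mode = mode, seed = seed)
  co
}

# draw an FC profile whose target correlation matrix is built from edge vector v
sample_fc_from_target <- function(v, r, n_time, floor = 1e-4) {
  target <- devectorize_upper(v, r)
  e <- eigen(target, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  spd <- e$vectors %*% (vals * t(e$vectors))
  spd <- stats::cov2cor(spd)
  ch <- chol(spd)
  ts <- matrix(stats::rnorm(n_time * r), n_time, r) %*% ch
  fc_profile(ts)
}

#' Synthetic 14-network ROI labeling
#'
#' Deterministically assigns `r` ROIs to `length(networks)` contiguous blocks
#' whose sizes are as equal as possible. The default names follow the
#' 14 functional networks of the Power parcellation; the labeling itself is
#' synthetic (no real ROI coordinates are shipped).
#'
#' @param r ROI count.
#' @param networks Character vector of network names.
#' @return Character vector of length `r`.
#' @export
synthetic_network_labels <- function(r, networks = power14_networks()) {
  k <- length(networks)
  if (r < k) stop("need at least as many ROIs as networks")
  sizes <- rep(r %/% k, k)
  sizes[seq_len(r %% k)] <- sizes[seq_len(r %% k)] + 1L
  rep(networks, times = sizes)
}

#' @rdname synthetic_network_labels
#' @export
power14_networks <- function() {
  c("FrontoParietal", "CinguloOpercular", "DorsalAttention", "VentralAttention",
    "Salience", "Cerebellum", "DMN", "Memory", "Visual", "Auditory",
    "SensorySomatomotorHand", "SensorySomatomotorMouth", "Subcortical",
    "Uncertain")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
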