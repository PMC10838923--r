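#' Run the full dyad-identification pipeline
#'
#' Orchestrates every stage on one cohort: whole-brain fingerprint
#' identification with its permutation test; the CBI model with both
#' sub-models, both metrics and both permutation tests; network-to-network
#' feature contributions (when ROI labels are available); and three
#' diffusion maps (whole-brain profiles under the Riemannian metric,
#' positive- and negative-feature profiles under the Euclidean metric) with
#' biological-vs-unrelated distance statistics. All randomness is driven by
#' `seed`: stage seeds are spawned deterministically, so reruns are
#' byte-identical. Defaults left open by the procedure (two-sided
#' t-approximation p-values, median-heuristic kernel scale, lowest-index tie
#' breaking) are recorded in the summary.
#'
#' @param cohort An [fc_cohort()], or a manifest CSV path for [read_cohort()].
#' @param out_dir Output directory; created if needed. `NULL` skips all file
#'   output and just returns the result list.
#' @param alpha Edgewise significance threshold (default 0.05).
#' @param n_perm Permutations per test (default 5000).
#' @param seed Top-level integer seed (default 1).
#' @param epsilon_scale Diffusion kernel scale multiplier (default 1).
#' @param shrinkage Ridge for the whole-brain SPD profiles (default 0.1;
#'   correlation matrices from fewer time points than ROIs are rank
#'   deficient).
#' @param stages Subset of `c("fingerprint", "cbi", "networks", "dmap")`.
#' @return Invisibly, a list with one entry per executed stage plus
#'   `summary`, the structure written to `summary.json`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, alpha = 0.05, n_perm = 5000,
                         seed = 1, epsilon_scale = 1, shrinkage = 0.1,
                         stages = c("fingerprint", "cbi", "networks", "dmap")) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "fc_cohort"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  stage_seed <- stats::setNames(
    sample.int(.Machine$integer.max - 1L, 4L),
    c("fingerprint", "cbi_labels", "cbi_features", "dmap"))

  res <- list()
  summary <- list(
    n_dyads = cohort$n_dyads, n_roi = cohort$n_roi, seed = seed,
    settings = list(alpha = alpha, n_perm = n_perm,
                    p_value_method = "two-sided t-approximation (df = n - 2)",
                    epsilon = "median of squared off-diagonal distances x scale",
                    epsilon_scale = epsilon_scale, shrinkage = shrinkage,
                    tie_break = "lowest index"))

  if ("fingerprint" %in% stages) {
    fp <- fingerprint(cohort)
    fp_perm <- fingerprint_permutation(fp, "parent-to-child", n_perm = n_perm,
                                       seed = stage_seed[["fingerprint"]])
    res$fingerprint <- list(fit = fp, permutation = fp_perm)
    summary$fingerprint <- list(
      parent_to_child_rate = fp$parent_to_child$rate,
      child_to_parent_rate = fp$child_to_parent$rate,
      permutation_p = fp_perm$p_value)
  }

  need_cbi <- any(c("cbi", "networks", "dmap") %in% stages)
  fit <- if (need_cbi) cbi(cohort, alpha = alpha)

  if ("cbi" %in% stages) {
    lab <- cbi_label_permutation(fit, n_perm = n_perm,
                                 seed = stage_seed[["cbi_labels"]])
    feat <- cbi_feature_permutation(cohort, n_perm = n_perm,
                                    seed = stage_seed[["cbi_features"]],
                                    alpha = alpha)
    res$cbi <- list(fit = fit, label_permutation = lab,
                    feature_permutation = feat)
    summary$cbi <- list(
      n_positive = sum(fit$features$pos),
      n_negative = sum(fit$features$neg),
      rates = fit$rates,
      label_permutation = lapply(lab, report_summary),
      feature_permutation = lapply(feat, report_summary))
  }

  if ("networks" %in% stages) {
    if (is.null(cohort$network_labels))
      stop("network stage requested but the cohort has no ROI network labels")
    nets <- list()
    for (sm in c("positive", "negative")) {
      if (sm %in% fit$unavailable) next
      nets[[sm]] <- network_contribution(fit, cohort$network_labels, sm)
    }
    res$networks <- nets
    summary$networks <- lapply(nets, function(nc)
      list(n_features = nc$n_features,
           top_node = top_node_label(nc$counts)))
  }

  if ("dmap" %in% stages) {
    roles <- rep(c("parent", "child"), each = cohort$n_dyads)
    dyads <- rep(cohort$dyad_ids, 2L)
    ids <- paste0(dyads, "_", roles)
    profiles <- c(cohort$parents, cohort$children)
    # true correlation matrices are PSD and any positive ridge suffices, but
    # directly simulated profiles need not be; raise the ridge when required
    gamma <- max(shrinkage, auto_shrinkage(profiles))
    dmaps <- list(
      whole_brain = diffusion_map(profiles,
                                  metric = "riemannian",
                                  epsilon_scale = epsilon_scale,
                                  shrinkage = gamma,
                                  roles = roles, dyads = dyads, ids = ids))
    for (sm in c("positive", "negative")) {
      if (is.null(fit[[sm]])) next
      prof <- rbind(fit[[sm]]$vectors$parents, fit[[sm]]$vectors$children)
      dmaps[[paste0(sm, "_features")]] <-
        diffusion_map(prof, metric = "euclidean",
                      epsilon_scale = epsilon_scale,
                      roles = roles, dyads = dyads, ids = ids)
    }
    stats <- lapply(dmaps, dyad_distance_stats)
    res$dmap <- list(maps = dmaps, stats = stats)
    summary$dmap <- lapply(stats, function(s)
      list(mean_bio = s$mean_bio, se_bio = s$se_bio,
           mean_unrel = s$mean_unrel, se_unrel = s$se_unrel,
           u_statistic = s$u_statistic, p_value = s$p_value))
  }

  res$summary <- summary
  if (!is.null(out_dir)) write_pipeline_outputs(res, fit, cohort, out_dir)
  invisible(res)
}

report_summary <- function(r) {
  list(observed_rate = r$observed_rate, mean_rate = r$mean_rate,
       max_rate = r$max_rate, max_recurrence = r$max_recurrence,
       p_value = r$p_value)
}

# smallest ridge for which every shrunk profile has min eigenvalue >= floor
auto_shrinkage <- function(profiles, floor = 1e-2) {
  lam <- min(vapply(profiles, function(m)
    min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values),
    numeric(1)))
  if (lam >= floor) return(0)
  (floor - lam) / (1 - lam)
}

top_node_label <- function(counts) {
  ut <- which(upper.tri(counts, diag = TRUE), arr.ind = TRUE)
  k <- ut[which.max(counts[ut]), ]
  paste0(rownames(counts)[k[1L]], "-", colnames(counts)[k[2L]])
}

write_pipeline_outputs <- function(res, fit, cohort, out_dir) {
  if (!is.null(res$cbi)) {
    utils::write.csv(coef(fit), file.path(out_dir, "cbi_features.csv"),
                     row.names = FALSE, quote = FALSE)
    for (sm in c("positive", "negative")) {
      if (is.null(fit[[sm]])) next
      for (met in c("euclidean", "spearman")) {
        utils::write.csv(as.data.frame(fit[[sm]][[met]]$values),
                         file.path(out_dir, sprintf("distance_%s_%s.csv", sm, met)),
                         row.names = FALSE)
      }
    }
  }
  if (!is.null(res$networks)) {
    for (sm in names(res$networks)) {
      nc <- res$networks[[sm]]
      for (what in c("counts", "fraction_of_total", "per_size")) {
        utils::write.csv(nc[[what]],
                         file.path(out_dir, sprintf("network_%s_%s.csv", sm, what)))
      }
    }
  }
  if (!is.null(res$dmap)) {
    for (nm in names(res$dmap$maps)) {
      dm <- res$dmap$maps[[nm]]
      utils::write.csv(
        data.frame(subject_id = dm$ids, role = dm$roles, dyad_id = dm$dyads,
                   c1 = dm$coordinates[, 1L], c2 = dm$coordinates[, 2L]),
        file.path(out_dir, sprintf("dmap_%s_coords.csv", nm)),
        row.names = FALSE, quote = FALSE)
    }
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
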