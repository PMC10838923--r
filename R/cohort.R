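#' Assemble a dyad cohort of parent and child FC profiles
#'
#' A cohort holds two index-aligned sets of FC profiles: `parents[[i]]` and
#' `children[[i]]` belong to the same biological dyad `dyad_ids[i]`. Every
#' identification model in the package exploits this alignment: in all
#' parents-by-children matrices the diagonal encodes the biological couples.
#'
#' @param parents,children Lists of FC profile matrices (equal length, equal
#'   dimension), each passing [validate_fc_profile()].
#' @param dyad_ids Character vector of dyad identifiers; defaults to
#'   `"d01"`, `"d02"`, ...
#' @param network_labels Optional factor/character vector of length `r`
#'   assigning each ROI to a named functional network.
#' @return Object of class `"fc_cohort"`: a list with elements `parents`,
#'   `children`, `dyad_ids`, `network_labels`, `n_dyads`, `n_roi`.
#' @export
fc_cohort <- function(parents, children, dyad_ids = NULL, network_labels = NULL) {
  if (length(parents) != length(children))
    stop("parent and child sets must have equal size (",
         length(parents), " vs ", length(children), ")")
  n <- length(parents)
  if (n < 2L) stop("a cohort needs at least 2 dyads")
  for (p in c(parents, children)) validate_fc_profile(p)
  r <- nrow(parents[[1L]])
  dims <- vapply(c(parents, children), nrow, integer(1))
  if (any(dims != r)) stop("all profiles must share the same ROI count")
  if (is.null(dyad_ids)) dyad_ids <- sprintf("d%02d", seq_len(n))
  dyad_ids <- as.character(dyad_ids)
  if (length(dyad_ids) != n) stop("dyad_ids length must equal the number of dyads")
  if (anyDuplicated(dyad_ids)) stop("dyad_ids must be unique")
  if (!is.null(network_labels)) {
    if (length(network_labels) != r)
      stop("network_labels must have one entry per ROI (", r, ")")
    network_labels <- as.character(network_labels)
    if (anyNA(network_labels)) stop("every ROI must be labeled")
  }
  structure(
    list(parents = parents, children = children, dyad_ids = dyad_ids,
         network_labels = network_labels, n_dyads = n, n_roi = r),
    class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat("FC cohort: ", x$n_dyads, " parent-child dyads, ",
      x$n_roi, " ROIs (", x$n_roi * (x$n_roi - 1L) / 2L, " edges)\n", sep = "")
  if (!is.null(x$network_labels))
    cat("Networks:  ", length(unique(x$network_labels)), " labels\n", sep = "")
  invisible(x)
}

# n_dyads x n_edges matrix of vectorized profiles for one role
cohort_edge_matrix <- function(cohort, role = c("parents", "children")) {
  role <- match.arg(role)
  do.call(rbind, lapply(cohort[[role]], vectorize_upper))
}

#' Read a delimited ROI time-series table
#'
#' Plain-text table, rows = time points, columns = ROIs; tab or comma
#' separated (auto-detected), optional header row.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` auto-detects between tab and comma.
#' @return Numeric matrix (time points by ROIs).
#' @export
read_time_series <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  header <- is.na(suppressWarnings(as.numeric(strsplit(first, sep, fixed = TRUE)[[1L]][1L])))
  m <- as.matrix(utils::read.table(path, sep = sep, header = header))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Write / read an FC profile as delimited text
#'
#' The full symmetric matrix is written tab-separated with 17 significant
#' digits so that write-then-read round-trips exactly.
#'
#' @param m FC profile matrix.
#' @param path Destination / source file path.
#' @return `read_fc_profile` returns the matrix; `write_fc_profile` returns
#'   `path` invisibly.
#' @export
write_fc_profile <- function(m, path) {
  lines <- apply(m, 1L, function(row) paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fc_profile
#' @export
read_fc_profile <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' Read an ROI-to-network label table
#'
#' CSV with header `roi_index,network`; `roi_index` is 0-based in the file
#' (the on-disk convention) and translated to 1-based positions internally.
#'
#' @param path Label CSV path.
#' @param r Optional expected ROI count, validated if given.
#' @return Character vector of network names ordered by ROI.
#' @export
read_network_labels <- function(path, r = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("roi_index", "network") %in% names(d)))
    stop("label file needs columns roi_index,network")
  d <- d[order(d$roi_index), ]
  if (!identical(as.integer(d$roi_index), seq_len(nrow(d)) - 1L))
    stop("roi_index must be 0-based and cover every ROI exactly once")
  if (!is.null(r) && nrow(d) != r)
    stop("label file has ", nrow(d), " ROIs, expected ", r)
  as.character(d$network)
}

#' Write an ROI-to-network label table
#'
#' @param labels Character vector of network names ordered by ROI.
#' @param path Destination CSV path (0-based `roi_index` column).
#' @export
write_network_labels <- function(labels, path) {
  utils::write.csv(
    data.frame(roi_index = seq_along(labels) - 1L, network = labels),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort to disk as per-subject files plus a manifest
#'
#' The manifest is a CSV with columns `subject_id,role,dyad_id,path`
#' (paths relative to the manifest); each subject's FC profile is written
#' with [write_fc_profile()]. Network labels, when present, are written
#' alongside as `network_labels.csv`.
#'
#' @param cohort An [fc_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (k in seq_len(cohort$n_dyads)) {
    for (role in c("parent", "child")) {
      sid <- paste0(cohort$dyad_ids[k], "_", role)
      rel <- paste0(sid, ".tsv")
      prof <- if (role == "parent") cohort$parents[[k]] else cohort$children[[k]]
      write_fc_profile(prof, file.path(dir, rel))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, role = role, dyad_id = cohort$dyad_ids[k], path = rel)
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$network_labels))
    write_network_labels(cohort$network_labels, file.path(dir, "network_labels.csv"))
  invisible(manifest)
}

#' Read a cohort from a manifest
#'
#' Accepts the layout written by [write_cohort()]: a manifest CSV with columns
#' `subject_id,role,dyad_id,path` pointing either at FC profile matrices or at
#' ROI time-series tables (`type = "timeseries"`, converted via [fc_profile()]).
#'
#' @param manifest Manifest CSV path.
#' @param type `"profile"` (default) or `"timeseries"`.
#' @param labels Optional path to a network label CSV; defaults to
#'   `network_labels.csv` next to the manifest when that file exists.
#' @return An [fc_cohort()].
#' @export
read_cohort <- function(manifest, type = c("profile", "timeseries"), labels = NULL) {
  type <- match.arg(type)
  d <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "role", "dyad_id", "path")
  if (!all(need %in% names(d)))
    stop("manifest needs columns ", paste(need, collapse = ","))
  if (!all(d$role %in% c("parent", "child")))
    stop("manifest roles must be 'parent' or 'child'")
  base <- dirname(manifest)
  dyads <- unique(d$dyad_id)
  load_one <- function(row) {
    f <- file.path(base, row$path)
    if (type == "profile") read_fc_profile(f)
    else fc_profile(read_time_series(f), subject_id = row$subject_id)
  }
  parents <- children <- vector("list", length(dyads))
  for (k in seq_along(dyads)) {
    sub <- d[d$dyad_id == dyads[k], ]
    if (!setequal(sub$role, c("parent", "child")) || nrow(sub) != 2L)
      stop("dyad ", dyads[k], " must have exactly one parent and one child")
    parents[[k]] <- load_one(sub[sub$role == "parent", ])
    children[[k]] <- load_one(sub[sub$role == "child", ])
  }
  if (is.null(labels)) {
    default <- file.path(base, "network_labels.csv")
    if (file.exists(default)) labels <- default
  }
  nl <- if (!is.null(labels)) read_network_labels(labels, r = nrow(parents[[1L]]))
  fc_cohort(parents, children, dyad_ids = dyads, network_labels = nl)
}
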