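#' Proximity-based association threshold
#'
#' Two fish are treated as associating when they are within a set number of
#' mean body lengths of each other. This computes that distance threshold per
#' group: `multiplier` times the mean standard body length of all fish in the
#' group, converted from mm to cm.
#'
#' @param body_lengths Tibble with columns `group_id, fish_id,
#'   standard_length_mm`; lengths strictly positive.
#' @param multiplier Threshold in units of mean body length; must be
#'   strictly positive. Default 2.
#'
#' @return Tibble with columns `group_id, mean_body_length_mm, threshold_cm`.
#' @examples
#' bl <- tibble::tibble(group_id = "g1", fish_id = 1:7, standard_length_mm = 36.98)
#' association_threshold(bl) # 2 x 36.98 mm = 7.396 cm
#' @export
association_threshold <- function(body_lengths, multiplier = 2) {
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier <= 0) {
    abort("`multiplier` must be a single strictly positive number")
  }
  if (!is.data.frame(body_lengths) || nrow(body_lengths) == 0L) {
    abort("`body_lengths` must be a non-empty data frame")
  }
  missing <- setdiff(c("group_id", "standard_length_mm"), names(body_lengths))
  if (length(missing) > 0L) {
    abort(paste0("`body_lengths` is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(body_lengths$standard_length_mm)) ||
      any(body_lengths$standard_length_mm <= 0)) {
    abort("standard lengths must be finite and strictly positive")
  }
  body_lengths |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(mean_body_length_mm = mean(.data$standard_length_mm),
                     .groups = "drop") |>
    dplyr::mutate(threshold_cm = multiplier * .data$mean_body_length_mm / 10)
}

# 0/1 adjacency from a distance matrix (inclusive boundary)
threshold_adjacency <- function(d, threshold_cm, include_boundary = TRUE) {
  adj <- if (include_boundary) (d <= threshold_cm) else (d < threshold_cm)
  storage.mode(adj) <- "integer"
  diag(adj) <- 0L
  adj
}

#' Binary association matrix for one frame
#'
#' Links every pair of fish whose Euclidean distance is within
#' `threshold_cm` (boundary inclusive by default: a pair exactly at the
#' threshold counts as associating).
#'
#' @inheritParams frame_geometry
#' @param threshold_cm Association distance in cm (see
#'   [association_threshold()]); must be strictly positive.
#' @param include_boundary Should a distance exactly equal to the threshold
#'   count as associating? Default `TRUE`.
#'
#' @return Symmetric 0/1 integer matrix with zero diagonal.
#' @examples
#' xy <- cbind(c(0, 5, 40), c(0, 0, 20))
#' association_matrix(xy, threshold_cm = 7.396)
#' @export
association_matrix <- function(positions, threshold_cm, include_boundary = TRUE) {
  if (!is.numeric(threshold_cm) || length(threshold_cm) != 1L || threshold_cm <= 0) {
    abort("`threshold_cm` must be a single strictly positive number")
  }
  threshold_adjacency(pairwise_distances(positions), threshold_cm, include_boundary)
}

check_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) abort("adjacency must be square")
  if (!all(adj %in% c(0L, 1L))) abort("adjacency entries must be 0/1")
  if (!isTRUE(all.equal(adj, t(adj), check.attributes = FALSE))) {
    abort("adjacency must be symmetric")
  }
  if (any(diag(adj) != 0)) abort("adjacency diagonal must be zero")
  invisible(adj)
}

#' Association-network density
#'
#' The sociability of a shoal in one frame: the number of associating pairs
#' divided by the total number of possible pairs, `n (n - 1) / 2`. An
#' alternative reading — the number of individuals with at least one
#' association, over the number of possible pairs — is retained as
#' `mode = "individuals"`.
#'
#' @param adj Binary symmetric adjacency matrix, e.g. from
#'   [association_matrix()].
#' @param mode `"pairs"` (default, graph density in `[0, 1]`) or
#'   `"individuals"`.
#'
#' @return Scalar; in `[0, 1]` for `mode = "pairs"`.
#' @examples
#' adj <- association_matrix(cbind(c(0, 1, 2), c(0, 0, 0)), threshold_cm = 1.5)
#' network_density(adj)
#' @export
network_density <- function(adj, mode = c("pairs", "individuals")) {
  mode <- match.arg(mode)
  check_adjacency(adj)
  n <- nrow(adj)
  if (n < 2L) abort("density needs at least 2 fish")
  possible <- n * (n - 1) / 2
  switch(mode,
    pairs = sum(adj) / 2 / possible,
    individuals = sum(rowSums(adj) > 0) / possible
  )
}

# connected-component sizes, sorted descending
component_sizes <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  sort(igraph::components(g)$csize, decreasing = TRUE)
}

#' Subgroup structure of an association network
#'
#' Partitions the fish of one frame into subgroups: the connected components
#' of the undirected association graph.
#'
#' @inheritParams network_density
#'
#' @return A list with `n_subgroups` (integer), `sizes` (component sizes
#'   sorted descending) and `membership` (integer component id per fish).
#' @examples
#' adj <- association_matrix(cbind(c(0, 1, 30), c(0, 0, 0)), threshold_cm = 2)
#' subgroups(adj) # one pair, one singleton
#' @export
subgroups <- function(adj) {
  check_adjacency(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)
  list(
    n_subgroups = comp$no,
    sizes = sort(as.integer(comp$csize), decreasing = TRUE),
    membership = as.integer(comp$membership)
  )
}

#' Association edge list for one frame
#'
#' Flattens a binary association matrix into a tidy edge list, the export
#' format for per-frame adjacency.
#'
#' @inheritParams network_density
#' @param frame_index Frame index to attach to every edge row.
#'
#' @return Tibble with columns `frame_index, fish_i, fish_j` (one row per
#'   associating pair, `fish_i < fish_j`).
#' @export
association_edges <- function(adj, frame_index = 0L) {
  check_adjacency(adj)
  up <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  tibble(frame_index = frame_index,
         fish_i = as.integer(up[, 1]),
         fish_j = as.integer(up[, 2]))
}
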