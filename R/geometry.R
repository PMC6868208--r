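#' @title Proximity and spatial metrics for a single frame
#'
#' @description Workhorse geometry operations on the fish positions of one
#' video frame. Each function accepts either a two-column numeric matrix of
#' `(x, y)` coordinates in cm or a data frame with columns `x_cm`/`y_cm`
#' (or `x`/`y`). All metrics are computed on the 2D top-down coordinates.
#'
#' @details
#' * `pairwise_distances()` returns the full symmetric matrix of Euclidean
#'   distances between fish.
#' * `nearest_neighbour_distances()` returns, for each fish, the distance to
#'   its closest group-mate.
#' * `cv_nearest_neighbour()` is the coefficient of variation (sample
#'   standard deviation over mean, divisor `n - 1`) of the within-frame
#'   nearest-neighbour distance vector: a dimensionless measure of how
#'   irregular the within-shoal spacing is.
#' * `expanse()` is the mean Euclidean distance of fish to the shoal's
#'   centre of mass (coordinate-wise mean position).
#' * `convex_hull_area()` is the area of the smallest convex polygon
#'   containing all fish; fewer than three distinct points, or collinear
#'   points, give area 0.
#' * `distance_to_nearest_wall()` is the distance from the shoal centroid to
#'   the nearest tank wall, the standard thigmotaxis measure: smaller values
#'   mean the group hugs the boundary.
#'
#' @param positions Fish coordinates for one frame: a data frame with
#'   `x_cm`/`y_cm` columns, or a numeric matrix with two columns.
#' @param tank A [tank_geometry()].
#' @name frame_geometry
#' @examples
#' square <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' pairwise_distances(square)
#' nearest_neighbour_distances(square) # all 1
#' expanse(square)                     # sqrt(2) / 2
#' convex_hull_area(square)            # 1
#' distance_to_nearest_wall(square, tank_geometry())
NULL

as_xy <- function(positions, min_fish = 2L) {
  if (is.data.frame(positions)) {
    xs <- intersect(c("x_cm", "x"), names(positions))
    ys <- intersect(c("y_cm", "y"), names(positions))
    if (length(xs) == 0L || length(ys) == 0L) {
      abort("`positions` data frame must contain x_cm/y_cm (or x/y) columns")
    }
    xy <- cbind(positions[[xs[1]]], positions[[ys[1]]])
  } else if (is.matrix(positions) && ncol(positions) >= 2L) {
    xy <- positions[, 1:2, drop = FALSE]
  } else {
    abort("`positions` must be a data frame or a matrix with >= 2 columns")
  }
  storage.mode(xy) <- "double"
  if (nrow(xy) < min_fish) {
    abort(sprintf("insufficient fish: need at least %d, got %d", min_fish, nrow(xy)))
  }
  if (!all(is.finite(xy))) abort("non-finite coordinate in frame")
  xy
}

#' @rdname frame_geometry
#' @return `pairwise_distances()`: a symmetric `n x n` matrix with zero
#'   diagonal, entries in cm.
#' @export
pairwise_distances <- function(positions) {
  xy <- as_xy(positions)
  as.matrix(dist(xy))
}

#' @rdname frame_geometry
#' @return `nearest_neighbour_distances()`: numeric vector of length
#'   `n_fish`, cm.
#' @export
nearest_neighbour_distances <- function(positions) {
  d <- pairwise_distances(positions)
  diag(d) <- Inf
  unname(apply(d, 1L, min))
}

#' @rdname frame_geometry
#' @return `cv_nearest_neighbour()`: dimensionless scalar >= 0.
#' @export
cv_nearest_neighbour <- function(positions) {
  nnd <- nearest_neighbour_distances(positions)
  m <- mean(nnd)
  if (m <= 0) abort("degenerate frame: all fish at identical positions (mean NND = 0)")
  sd(nnd) / m
}

#' @rdname frame_geometry
#' @return `expanse()`: mean distance to the centre of mass, cm.
#' @export
expanse <- function(positions) {
  xy <- as_xy(positions, min_fish = 1L)
  centre <- colMeans(xy)
  mean(sqrt((xy[, 1] - centre[1])^2 + (xy[, 2] - centre[2])^2))
}

#' @rdname frame_geometry
#' @return `convex_hull_area()`: hull area in cm^2 (0 for degenerate
#'   configurations).
#' @export
convex_hull_area <- function(positions) {
  xy <- as_xy(positions, min_fish = 1L)
  xy <- unique(xy)
  if (nrow(xy) < 3L) return(0)
  hull <- grDevices::chull(xy)
  if (length(hull) < 3L) return(0)
  hx <- xy[hull, 1]
  hy <- xy[hull, 2]
  # shoelace formula on the hull vertex cycle
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' @rdname frame_geometry
#' @return `distance_to_nearest_wall()`: cm, in `[0, min(length, width) / 2]`.
#' @export
distance_to_nearest_wall <- function(positions, tank) {
  tank <- as_tank(tank)
  xy <- as_xy(positions, min_fish = 1L)
  centre <- colMeans(xy)
  if (centre[1] < 0 || centre[1] > tank$length_cm ||
      centre[2] < 0 || centre[2] > tank$width_cm) {
    abort(sprintf(
      "position outside tank: centroid (%.2f, %.2f) not in [0, %g] x [0, %g]",
      centre[1], centre[2], tank$length_cm, tank$width_cm
    ))
  }
  min(centre[1], tank$length_cm - centre[1], centre[2], tank$width_cm - centre[2])
}

# breadth-first component sizes on a 0/1 adjacency; hot-path replacement for
# the igraph route in subgroups() (identical output, no graph construction)
bfs_component_sizes <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      queue <- i
      comp[i] <- cid
      while (length(queue) > 0L) {
        v <- queue[[1L]]
        queue <- queue[-1L]
        nb <- which(adj[v, ] != 0L & comp == 0L)
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
  }
  tabulate(comp, nbins = cid)
}

# All per-frame metrics for one coordinate matrix; social metrics need the
# association threshold (cm). Returns an unnamed numeric vector in the
# column order of frame_metrics().
frame_metric_vector <- function(xy, tank, threshold_cm) {
  n <- nrow(xy)
  dx <- outer(xy[, 1], xy[, 1], "-")
  dy <- outer(xy[, 2], xy[, 2], "-")
  d <- sqrt(dx * dx + dy * dy)
  diag(d) <- Inf
  nnd <- do.call(pmin, lapply(seq_len(n), function(j) d[, j]))
  mean_nnd <- mean(nnd)
  if (mean_nnd <= 0) abort("degenerate frame: all fish at identical positions (mean NND = 0)")
  adj <- (d <= threshold_cm) * 1L
  comp <- bfs_component_sizes(adj)
  diag(d) <- 0
  cx <- mean(xy[, 1])
  cy <- mean(xy[, 2])
  c(
    mean_nnd,                                   # mean_nnd_cm
    sd(nnd) / mean_nnd,                         # cv_nnd
    sum(d) / (n * (n - 1)),                     # mean_interindividual_distance_cm
    mean(sqrt((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2)),  # expanse_cm
    convex_hull_area(xy),                       # convex_hull_area_cm2
    cx, cy,                                     # centroid_x_cm, centroid_y_cm
    min(cx, tank$length_cm - cx, cy, tank$width_cm - cy),  # distance_to_wall_cm
    sum(adj) / (n * (n - 1)),                   # density
    length(comp),                               # n_subgroups
    max(comp)                                   # largest_subgroup_size
  )
}

validate_positions <- function(positions, tank) {
  required <- c("group_id", "condition", "frame_index", "fish_id", "x_cm", "y_cm")
  missing <- setdiff(required, names(positions))
  if (length(missing) > 0L) {
    abort(paste0("`positions` is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!all(is.finite(positions$x_cm)) || !all(is.finite(positions$y_cm))) {
    abort("non-finite coordinate in `positions`")
  }
  if (any(positions$x_cm < 0 | positions$x_cm > tank$length_cm) ||
      any(positions$y_cm < 0 | positions$y_cm > tank$width_cm)) {
    abort("position outside tank bounds")
  }
  invisible(positions)
}

#' Per-frame shoal metrics for a whole study
#'
#' Computes every proximity, spatial and social metric for each frame of a
#' long-format position table, one row per group x condition x frame. Social
#' metrics (association-network density and subgroup structure) use a
#' proximity threshold of `multiplier` mean body lengths, computed per group
#' from `body_lengths`.
#'
#' @param positions Long-format tibble of fish positions with columns
#'   `group_id, condition, frame_index, fish_id, x_cm, y_cm` (a `time_s`
#'   column, if present, is carried through unused).
#' @param tank A [tank_geometry()].
#' @param body_lengths Tibble with columns `group_id, fish_id,
#'   standard_length_mm` (see [association_threshold()]).
#' @param multiplier Association threshold in units of mean body length
#'   (default 2).
#'
#' @return A tibble with one row per frame and columns `group_id, condition,
#'   frame_index, mean_nnd_cm, cv_nnd, mean_interindividual_distance_cm,
#'   expanse_cm, convex_hull_area_cm2, centroid_x_cm, centroid_y_cm,
#'   distance_to_wall_cm, density, n_subgroups, largest_subgroup_size`.
#' @examples
#' study <- simulate_study(simulation_config(n_groups = 2, n_frames = 10), seed = 1)
#' frame_metrics(study$positions, tank_geometry(), study$body_lengths)
#' @export
frame_metrics <- function(positions, tank = tank_geometry(), body_lengths,
                          multiplier = 2) {
  tank <- as_tank(tank)
  validate_positions(positions, tank)
  thresholds <- association_threshold(body_lengths, multiplier)
  thr <- stats::setNames(thresholds$threshold_cm, thresholds$group_id)
  unknown <- setdiff(unique(positions$group_id), names(thr))
  if (length(unknown) > 0L) {
    abort(paste0("no body lengths for group(s): ", paste(unknown, collapse = ", ")))
  }

  ord <- order(positions$group_id, positions$condition, positions$frame_index)
  positions <- positions[ord, ]
  key <- paste(positions$group_id, positions$condition, positions$frame_index,
               sep = "\r")
  idx <- split(seq_len(nrow(positions)), factor(key, levels = unique(key)))

  metric_cols <- c("mean_nnd_cm", "cv_nnd", "mean_interindividual_distance_cm",
                   "expanse_cm", "convex_hull_area_cm2", "centroid_x_cm",
                   "centroid_y_cm", "distance_to_wall_cm", "density",
                   "n_subgroups", "largest_subgroup_size")
  out <- matrix(NA_real_, nrow = length(idx), ncol = length(metric_cols),
                dimnames = list(NULL, metric_cols))
  first <- vapply(idx, `[[`, integer(1), 1L)
  x <- positions$x_cm
  y <- positions$y_cm
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    if (length(i) < 2L) abort("insufficient fish: a frame has fewer than 2 fish")
    if (anyDuplicated(positions$fish_id[i])) abort("duplicate fish_id within a frame")
    xy <- cbind(x[i], y[i])
    out[k, ] <- frame_metric_vector(xy, tank,
                                    thr[[as.character(positions$group_id[i[1L]])]])
  }
  dplyr::bind_cols(
    tibble(group_id = positions$group_id[first],
           condition = positions$condition[first],
           frame_index = positions$frame_index[first]),
    as_tibble(out)
  ) |>
    dplyr::mutate(n_subgroups = as.integer(.data$n_subgroups),
                  largest_subgroup_size = as.integer(.data$largest_subgroup_size))
}
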