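# Brute-force oracles, independent of the package's implementation paths,
# plus small fixture generators. Everything is built in code at test time.

oracle_pairwise <- function(xy) {
  n <- nrow(xy)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2)
    }
  }
  d
}

oracle_nnd <- function(xy) {
  d <- oracle_pairwise(xy)
  n <- nrow(xy)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- min(d[i, -i])
  out
}

oracle_expanse <- function(xy) {
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  mean(sqrt((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2))
}

# hull area by exhaustive vertex filtering: a point is a hull vertex iff it
# is not strictly inside the triangle of any three other points; then the
# shoelace formula on the angularly sorted vertices
oracle_hull_area <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  if (n < 3L) return(0)
  in_triangle <- function(p, a, b, c) {
    s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
    s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
    (s1 > 1e-12 & s2 > 1e-12 & s3 > 1e-12) |
      (s1 < -1e-12 & s2 < -1e-12 & s3 < -1e-12)
  }
  vertex <- rep(TRUE, n)
  for (p in seq_len(n)) {
    others <- setdiff(seq_len(n), p)
    combs <- utils::combn(others, 3)
    for (k in seq_len(ncol(combs))) {
      if (in_triangle(xy[p, ], xy[combs[1, k], ], xy[combs[2, k], ],
                      xy[combs[3, k], ])) {
        vertex[p] <- FALSE
        break
      }
    }
  }
  v <- xy[vertex, , drop = FALSE]
  if (nrow(v) < 3L) return(0)
  cx <- mean(v[, 1]); cy <- mean(v[, 2])
  v <- v[order(atan2(v[, 2] - cy, v[, 1] - cx)), , drop = FALSE]
  hx <- v[, 1]; hy <- v[, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# connected components by union-find
oracle_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find2 <- function(i, parent) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (adj[i, j] == 1L) {
        ri <- find2(i, parent); rj <- find2(j, parent)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find2, integer(1), parent = parent)
  sort(as.integer(table(roots)), decreasing = TRUE)
}

random_frame <- function(n_fish = 7, tank = tank_geometry()) {
  cbind(runif(n_fish, 0, tank$length_cm), runif(n_fish, 0, tank$width_cm))
}

# long-format position tibble wrapping one coordinate matrix per frame
frames_to_positions <- function(frames, group_id = "g01",
                                condition = "immediate") {
  purrr::map_dfr(seq_along(frames), function(k) {
    xy <- frames[[k]]
    tibble::tibble(
      group_id = group_id, condition = condition, frame_index = k - 1L,
      time_s = (k - 1L) * 10, fish_id = seq_len(nrow(xy)),
      x_cm = xy[, 1], y_cm = xy[, 2]
    )
  })
}

uniform_body_lengths <- function(group_ids, length_mm = 37, n_fish = 7) {
  tibble::tibble(
    group_id = rep(group_ids, each = n_fish),
    fish_id = rep(seq_len(n_fish), times = length(group_ids)),
    standard_length_mm = length_mm
  )
}

# paired observation table with a known condition shift and group effects,
# iid within cells: the null/power generator for the LRT calibration tests
paired_gaussian_table <- function(n_groups, n_per_cell, shift = 0,
                                  group_sd = 1, resid_sd = 1) {
  g <- sprintf("g%02d", seq_len(n_groups))
  b <- rnorm(n_groups, 0, group_sd)
  tibble::tibble(
    group_id = rep(rep(g, each = n_per_cell), times = 2),
    condition = rep(c("immediate", "after_24h"), each = n_groups * n_per_cell),
    value = c(rnorm(n_groups * n_per_cell, rep(b, each = n_per_cell) + shift, resid_sd),
              rnorm(n_groups * n_per_cell, rep(b, each = n_per_cell), resid_sd))
  )
}

paired_binomial_table <- function(n_groups, n_per_cell, logit_shift = 0,
                                  group_sd = 0.5, base_logit = 0) {
  g <- sprintf("g%02d", seq_len(n_groups))
  b <- rnorm(n_groups, 0, group_sd)
  eta1 <- rep(b, each = n_per_cell) + base_logit + logit_shift
  eta2 <- rep(b, each = n_per_cell) + base_logit
  tibble::tibble(
    group_id = rep(rep(g, each = n_per_cell), times = 2),
    condition = rep(c("immediate", "after_24h"), each = n_groups * n_per_cell),
    present = c(rbinom(n_groups * n_per_cell, 1, stats::plogis(eta1)),
                rbinom(n_groups * n_per_cell, 1, stats::plogis(eta2)))
  )
}

fast_glmm_control <- function() {
  lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE,
                     check.conv.singular = "ignore")
}

fast_lmm_control <- function() {
  lme4::lmerControl(calc.derivs = FALSE, check.conv.singular = "ignore")
}
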