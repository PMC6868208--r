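square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))

test_that("pairwise distances match hand geometry and the loop oracle", {
  expect_equal(pairwise_distances(cbind(c(0, 3), c(0, 4)))[1, 2], 5)

  set.seed(41)
  for (rep in 1:20) {
    xy <- random_frame(7)
    d <- pairwise_distances(xy)
    expect_equal(d, oracle_pairwise(xy), ignore_attr = TRUE, tolerance = 1e-12)
    expect_identical(d, t(d))
    expect_true(all(diag(d) == 0))
  }

  expect_error(pairwise_distances(cbind(1, 2)), "insufficient fish")
  expect_error(pairwise_distances(cbind(c(0, NA), c(0, 1))), "non-finite")
})

test_that("nearest-neighbour distances are the row-wise minima", {
  expect_equal(nearest_neighbour_distances(square), rep(1, 4))
  expect_equal(nearest_neighbour_distances(cbind(c(0, 1, 3), c(0, 0, 0))),
               c(1, 1, 2))

  set.seed(42)
  for (rep in 1:20) {
    xy <- random_frame(7)
    expect_equal(nearest_neighbour_distances(xy), oracle_nnd(xy),
                 tolerance = 1e-12)
  }
})

test_that("CV of NND uses the sample SD and is scale-free", {
  expect_equal(cv_nearest_neighbour(square), 0)
  # NND vector (1, 1, 2): mean 4/3, sample sd sqrt(1/3)
  collinear <- cbind(c(0, 1, 3), c(0, 0, 0))
  expect_equal(cv_nearest_neighbour(collinear), sqrt(1 / 3) / (4 / 3),
               tolerance = 1e-10)
  expect_equal(cv_nearest_neighbour(collinear), 0.4330127, tolerance = 1e-6)

  set.seed(43)
  xy <- random_frame(7)
  expect_equal(cv_nearest_neighbour(xy * 3.7), cv_nearest_neighbour(xy),
               tolerance = 1e-12)
  expect_error(cv_nearest_neighbour(rbind(c(1, 1), c(1, 1))), "degenerate")
})

test_that("expanse equals the mean distance to the centre of mass", {
  expect_equal(expanse(square), sqrt(2) / 2)
  expect_equal(expanse(cbind(5, 5)), 0)
  set.seed(44)
  for (rep in 1:20) {
    xy <- random_frame(7)
    expect_equal(expanse(xy), oracle_expanse(xy), tolerance = 1e-12)
  }
})

test_that("convex hull area matches the exhaustive hull oracle", {
  expect_equal(convex_hull_area(square), 1)
  expect_equal(convex_hull_area(cbind(c(0, 1, 3), c(0, 0, 0))), 0)
  expect_equal(convex_hull_area(rbind(c(1, 1), c(2, 2))), 0)

  set.seed(45)
  for (rep in 1:30) {
    xy <- random_frame(7)
    expect_equal(convex_hull_area(xy), oracle_hull_area(xy), tolerance = 1e-9)
  }
})

test_that("distance to nearest wall is the minimum of the four wall distances", {
  tank <- tank_geometry(45, 25, 20)
  expect_equal(distance_to_nearest_wall(cbind(22.5, 12.5), tank), 12.5)
  expect_equal(distance_to_nearest_wall(cbind(1, 10), tank), 1)
  expect_error(distance_to_nearest_wall(cbind(50, 10), tank), "outside tank")

  set.seed(46)
  for (rep in 1:100) {
    c_xy <- c(runif(1, 0, 45), runif(1, 0, 25))
    expect_equal(
      distance_to_nearest_wall(rbind(c_xy), tank),
      min(c_xy[1], 45 - c_xy[1], c_xy[2], 25 - c_xy[2])
    )
  }
})

test_that("distance metrics are invariant under rigid motion", {
  set.seed(47)
  xy <- random_frame(7)
  ang <- 0.7
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  moved <- sweep(xy %*% rot, 2, c(3, 2), "+")
  expect_equal(pairwise_distances(moved), pairwise_distances(xy),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(expanse(moved), expanse(xy), tolerance = 1e-10)
  expect_equal(convex_hull_area(moved), convex_hull_area(xy), tolerance = 1e-9)
  expect_equal(cv_nearest_neighbour(moved), cv_nearest_neighbour(xy),
               tolerance = 1e-10)
})

test_that("frame_metrics populates every field consistently with per-metric calls", {
  tank <- tank_geometry()
  bl <- uniform_body_lengths("g01", length_mm = 40, n_fish = 4)
  # unit square placed mid-tank; huge threshold via multiplier
  frames <- list(sweep(square, 2, c(20, 10), "+"))
  pos <- frames_to_positions(frames)
  m <- frame_metrics(pos, tank, bl, multiplier = 10) # threshold 40 cm
  expect_equal(nrow(m), 1L)
  expect_equal(m$density, 1)
  expect_equal(m$n_subgroups, 1L)
  expect_equal(m$largest_subgroup_size, 4L)
  expect_equal(m$convex_hull_area_cm2, 1)
  expect_equal(m$cv_nnd, 0)
  expect_equal(m$centroid_x_cm, 20.5)
  expect_equal(m$distance_to_wall_cm, 10.5)

  # coincident-pair-ish cluster + distant pair: fields match independent calls
  xy <- rbind(c(5, 5), c(5.5, 5), c(40, 20), c(40.5, 20))
  pos2 <- frames_to_positions(list(xy))
  m2 <- frame_metrics(pos2, tank, uniform_body_lengths("g01", 40, 4),
                      multiplier = 2) # threshold 8 cm
  expect_equal(m2$mean_nnd_cm, mean(nearest_neighbour_distances(xy)))
  expect_equal(m2$cv_nnd, cv_nearest_neighbour(xy))
  expect_equal(m2$expanse_cm, expanse(xy))
  expect_equal(m2$convex_hull_area_cm2, convex_hull_area(xy))
  expect_equal(m2$distance_to_wall_cm, distance_to_nearest_wall(xy, tank))
  adj <- association_matrix(xy, 8)
  expect_equal(m2$density, network_density(adj))
  expect_equal(m2$n_subgroups, subgroups(adj)$n_subgroups)
  expect_equal(m2$largest_subgroup_size, max(subgroups(adj)$sizes))
  expect_equal(m2$mean_interindividual_distance_cm,
               mean(pairwise_distances(xy)[upper.tri(diag(4))]))
})

test_that("mean NND never exceeds the mean inter-individual distance", {
  set.seed(48)
  tank <- tank_geometry()
  bl <- uniform_body_lengths("g01")
  frames <- replicate(25, random_frame(7), simplify = FALSE)
  m <- frame_metrics(frames_to_positions(frames), tank, bl)
  expect_true(all(m$mean_nnd_cm <= m$mean_interindividual_distance_cm + 1e-12))
  expect_true(all(m$density >= 0 & m$density <= 1))
  expect_true(all(m$n_subgroups >= 1 & m$n_subgroups <= 7))
})

test_that("frame_metrics validates its inputs", {
  tank <- tank_geometry()
  bl <- uniform_body_lengths("g01")
  pos <- frames_to_positions(list(random_frame(7)))
  expect_error(frame_metrics(dplyr::select(pos, -"x_cm"), tank, bl), "missing columns")
  bad <- pos; bad$x_cm[1] <- 99
  expect_error(frame_metrics(bad, tank, bl), "outside tank")
  bad2 <- pos; bad2$fish_id[2] <- bad2$fish_id[1]
  expect_error(frame_metrics(bad2, tank, bl), "duplicate fish_id")
  expect_error(frame_metrics(pos, tank, uniform_body_lengths("zz")), "no body lengths")
})
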