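small_config <- function(...) {
  simulation_config(n_groups = 2, n_frames = 12, ...)
}

test_that("the same seed reproduces the trajectory bit for bit", {
  cfg <- small_config()
  t1 <- simulate_shoal(cfg, "g01", "immediate", seed = 5)
  t2 <- simulate_shoal(cfg, "g01", "immediate", seed = 5)
  expect_identical(t1$positions, t2$positions)
  t3 <- simulate_shoal(cfg, "g01", "immediate", seed = 6)
  expect_false(identical(t1$positions, t3$positions))

  s1 <- simulate_study(small_config(), seed = 3)
  s2 <- simulate_study(small_config(), seed = 3)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$behaviour, s2$behaviour)
  expect_identical(s1$cortisol, s2$cortisol)
})

test_that("all generated positions respect the tank bounds", {
  cfg <- small_config()
  study <- simulate_study(cfg, seed = 4)
  expect_true(all(study$positions$x_cm >= 0 & study$positions$x_cm <= 45))
  expect_true(all(study$positions$y_cm >= 0 & study$positions$y_cm <= 25))
  expect_true(all(study$positions$z_cm >= 0 & study$positions$z_cm <= 20))
  expect_true(all(study$behaviour$present %in% c(0L, 1L)))
  # shapes follow the config
  expect_equal(nrow(study$positions), 2 * 2 * 12 * 7)
  expect_equal(nrow(study$behaviour), 2 * 2 * 12 * 2)
  expect_equal(nrow(study$cortisol), 2 * 2)
})

test_that("zero weights and zero noise freeze the fish at their release points", {
  cfg <- small_config(
    w_att = 0, kappa = 0, w_rep = 0, w_wall = 0, w_wall_base = 0,
    detach_rate = 0, return_rate = 0, depth_w0 = 0, depth_w1 = 0,
    sigma_xy = 0, sigma_z = 0, p0_err = 0
  )
  traj <- simulate_shoal(cfg, "g01", "immediate", seed = 7)
  expect_equal(max(abs(sweep(traj$positions, 2,
                             traj$positions[1, ], "-"))), 0)
  # and the derived behaviours are all absent / all below half depth as placed
  beh <- derive_behaviour_table(traj)
  expect_true(all(beh$present[beh$behaviour == "erratic_movement"] == 0L))
})

test_that("behaviour derivation scores speed bursts and top-half excursions", {
  cfg <- small_config()
  # hand-built trajectory: 2 fish, 2 clips of 10 s at 10 subframes/s
  cfg2 <- simulation_config(n_groups = 1, n_fish = 2, n_frames = 2)
  n_steps <- 2 * 10 * 10
  pos <- matrix(0, n_steps + 1, 6)
  pos[, 1] <- 10; pos[, 2] <- 12   # x
  pos[, 3] <- 10; pos[, 4] <- 12   # y
  pos[, 5:6] <- 5                  # z below half depth
  # one fast jump for fish 1 inside clip 2 (speed 60 cm/s over dt = 0.1)
  pos[150:(n_steps + 1), 1] <- 10 + 6
  # one top-half excursion for fish 2 inside clip 1
  pos[30, 6] <- 15
  traj <- structure(
    list(positions = pos, dt = 0.1, group_id = "g01",
         condition = "immediate", config = cfg2),
    class = "shoal_trajectory"
  )
  beh <- derive_behaviour_table(traj)
  err <- beh$present[beh$behaviour == "erratic_movement"]
  top <- beh$present[beh$behaviour == "top_half"]
  expect_equal(err, c(0L, 1L))
  expect_equal(top, c(1L, 0L))
})

test_that("stressed shoals are denser, wall-bound, erratic and bottom-dwelling", {
  cfg <- simulation_config(n_frames = 60)
  seeds <- 1:8
  per_condition <- function(cond) {
    sapply(seeds, function(s) {
      traj <- simulate_shoal(cfg, "g01", cond, seed = s)
      fr <- trajectory_frames(traj)
      beh <- derive_behaviour_table(traj)
      frames <- split(fr, fr$frame_index)
      met <- sapply(frames, function(f) {
        xy <- cbind(f$x_cm, f$y_cm)
        c(density = network_density(association_matrix(xy, 7.4)),
          cv = cv_nearest_neighbour(xy),
          wall = distance_to_nearest_wall(xy, cfg$tank))
      })
      c(rowMeans(met),
        erratic = mean(beh$present[beh$behaviour == "erratic_movement"]),
        top = mean(beh$present[beh$behaviour == "top_half"]))
    })
  }
  hi <- rowMeans(per_condition("immediate"))
  lo <- rowMeans(per_condition("after_24h"))
  expect_gt(hi[["density"]], lo[["density"]])
  expect_lt(hi[["cv"]], lo[["cv"]])
  expect_lt(hi[["wall"]], lo[["wall"]])
  expect_gt(hi[["erratic"]], lo[["erratic"]])
  expect_lt(hi[["top"]], lo[["top"]])
})

test_that("cortisol draws hit their configured condition means", {
  cfg <- simulation_config()
  set.seed(91)
  means <- replicate(60, {
    ct <- simulate_cortisol(cfg)
    tapply(ct$cortisol_ng_per_g, ct$condition, mean)
  })
  grand <- rowMeans(means)
  # grand means within 2 SE of the targets (SE of the mean of 60 studies)
  se <- apply(means, 1, sd) / sqrt(ncol(means))
  expect_lt(abs(grand[["immediate"]] - 40.2), 2 * se[["immediate"]] + 1)
  expect_lt(abs(grand[["after_24h"]] - 19.9), 2 * se[["after_24h"]] + 1)

  # zero-variance config collapses to the exact condition means
  cfg0 <- simulation_config(cortisol_se = c(immediate = 0, after_24h = 0),
                            cortisol_group_tau = 0)
  ct0 <- simulate_cortisol(cfg0, seed = 1)
  expect_equal(unique(ct0$cortisol_ng_per_g[ct0$condition == "immediate"]), 40.2)
  expect_equal(unique(ct0$cortisol_ng_per_g[ct0$condition == "after_24h"]), 19.9)

  expect_identical(simulate_cortisol(cfg, seed = 2), simulate_cortisol(cfg, seed = 2))
})

test_that("study outputs round-trip losslessly through the CSV writers", {
  study <- simulate_study(small_config(), seed = 12)
  dir <- withr::local_tempdir()
  files <- write_study(study, dir)
  expect_true(all(file.exists(files)))
  pos <- read_positions(files[["positions"]])
  expect_equal(as.data.frame(pos), as.data.frame(study$positions),
               tolerance = 1e-12)
  beh <- read_behaviour(files[["behaviour"]])
  expect_equal(as.data.frame(beh), as.data.frame(study$behaviour))
  bl <- read_body_lengths(files[["body_lengths"]])
  expect_equal(as.data.frame(bl), as.data.frame(study$body_lengths),
               tolerance = 1e-12)
  ct <- read_cortisol(files[["cortisol"]])
  expect_equal(as.data.frame(ct), as.data.frame(study$cortisol),
               tolerance = 1e-12)
  prov <- jsonlite::read_json(files[["provenance"]])
  expect_equal(prov$seed, 12)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(theta = c(immediate = 2, after_24h = 0.2)),
               "\\[0, 1\\]")
  expect_error(simulation_config(w_att = -1), ">= 0")
  cfg <- small_config()
  expect_error(simulate_shoal(cfg, "g01", "weird", seed = 1), "unknown condition")
})
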