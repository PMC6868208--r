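#' Simulation configuration
#'
#' Parameters of the synthetic study generator. Defaults reproduce the
#' reference study design: 23 groups of 7 fish observed for 30 min per
#' condition in a 45 x 25 cm tank filled to 20 cm, positions sampled every
#' 10 s (180 frames), body lengths 36.98 +/- 2.24 mm, and whole-body
#' cortisol targeting condition means of 40.2 and 19.9 ng/g (SEs 6.0 and
#' 4.3 at n = 23).
#'
#' The motion model is a discrete-time zonal attraction/repulsion scheme
#' driven by a stress level `theta` in `[0, 1]` per condition (1 =
#' immediately after transfer to the novel tank, 0.2 = 24 h later): stress
#' tightens centroid attraction by a factor `(1 + kappa * theta)`, suppresses
#' excursions into an "independent" behavioural state (relaxed shoals have
#' stragglers, raising the spread and the variability of nearest-neighbour
#' spacing), strengthens the pull toward the nearest wall
#' (`w_wall_base + w_wall * theta`), biases depth downward
#' (`depth_w0 + depth_w1 * theta`) and raises the per-subframe probability
#' of an erratic burst (`p0_err * (1 + beta_err * theta)`), a large random
#' velocity impulse of magnitude `burst_speed`. Between-group heterogeneity
#' enters through lognormal/normal group traits shared by both conditions
#' of a group, which is what the group random intercept of the analysis
#' models absorb.
#'
#' @param n_groups Number of replicate shoals.
#' @param n_fish Fish per shoal.
#' @param n_frames Position frames retained per session.
#' @param frame_interval_s Seconds between retained frames.
#' @param subframes_per_s Simulation substeps per second (behaviour is
#'   derived at subframe resolution; frames are downsampled).
#' @param tank A [tank_geometry()].
#' @param body_length_mean_mm,body_length_sd_mm Standard-length distribution.
#' @param theta Named stress levels per condition.
#' @param w_att,kappa,w_rep,rep_radius,w_wall,w_wall_base,depth_w0,depth_w1,sigma_xy,sigma_z
#'   Interaction weights: centroid attraction rate (1/s) and its stress
#'   multiplier; short-range repulsion gain (1/s) and radius (cm); wall
#'   attraction (cm/s per unit theta) and its stress-independent baseline;
#'   depth drift base and stress slope (cm/s); velocity noise SDs (cm/s).
#' @param detach_rate,return_rate,indep_att Behavioural-state switching:
#'   cohesive fish become independent wanderers at `detach_rate * (1 -
#'   theta)` per second (so acutely stressed shoals cohere homogeneously
#'   while relaxed shoals have stragglers), return at `return_rate`, and
#'   while independent feel `indep_att` times the centroid attraction.
#' @param p0_err,beta_err,burst_speed Erratic-burst base probability per
#'   fish-subframe, its stress multiplier, and impulse speed (cm/s).
#' @param erratic_speed_cm_s,erratic_turn_rad Detection thresholds used by
#'   [derive_behaviour_table()]: a clip is scored erratic when any fish
#'   exceeds the speed threshold (or the turning-angle threshold, disabled
#'   by default) in any subframe.
#' @param trait_att_sdlog,trait_err_sdlog,trait_depth_sd,trait_wall_sdlog
#'   SDs of the per-group traits (lognormal multipliers on attraction,
#'   burst rate, wall pull; additive normal on depth drift).
#' @param cortisol_mean,cortisol_se Target condition means and standard
#'   errors (ng/g) of whole-body cortisol at `n_groups` fish per condition.
#' @param cortisol_group_tau SD (log scale) of the shared per-group cortisol
#'   effect.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_groups = 23, n_fish = 7, n_frames = 180,
                              frame_interval_s = 10, subframes_per_s = 10,
                              tank = tank_geometry(45, 25, 20),
                              body_length_mean_mm = 36.98,
                              body_length_sd_mm = 2.24,
                              theta = c(immediate = 1, after_24h = 0.2),
                              w_att = 0.09, kappa = 15,
                              w_rep = 1.5, rep_radius = 3,
                              w_wall = 0.55, w_wall_base = 0.24,
                              detach_rate = 0.12, return_rate = 0.2,
                              indep_att = 0.05,
                              depth_w0 = 1.58, depth_w1 = 1.87,
                              sigma_xy = 10, sigma_z = 10,
                              p0_err = 1.7e-4, beta_err = 15,
                              burst_speed = 70,
                              erratic_speed_cm_s = 50,
                              erratic_turn_rad = Inf,
                              trait_att_sdlog = 0.2,
                              trait_err_sdlog = 0.4,
                              trait_depth_sd = 0.25,
                              trait_wall_sdlog = 0.3,
                              cortisol_mean = c(immediate = 40.2, after_24h = 19.9),
                              cortisol_se = c(immediate = 6.0, after_24h = 4.3),
                              cortisol_group_tau = 0.3) {
  tank <- as_tank(tank)
  if (any(theta < 0 | theta > 1)) abort("`theta` must lie in [0, 1]")
  if (length(theta) != 2L || is.null(names(theta))) {
    abort("`theta` must be a named vector of 2 condition stress levels")
  }
  rates <- c(w_att, w_rep, w_wall, w_wall_base, detach_rate, return_rate,
             indep_att, p0_err, beta_err, sigma_xy, sigma_z,
             depth_w0, depth_w1, burst_speed)
  if (any(rates < 0)) abort("interaction weights and rates must be >= 0")
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

#' @exportS3Method base::print
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d groups x %d fish, %d frames every %g s (dt = %g s)\n",
    x$n_groups, x$n_fish, x$n_frames, x$frame_interval_s, 1 / x$subframes_per_s
  ))
  cat(sprintf("  theta: %s\n",
              paste(names(x$theta), x$theta, sep = " = ", collapse = ", ")))
  invisible(x)
}

# lognormal parameters hitting a target mean/SD, with the log-scale variance
# split into a shared group effect (tau) and a residual
cortisol_lognormal_params <- function(mean, sd, tau) {
  if (mean <= 0) abort("cortisol mean must be positive")
  s2 <- log(1 + (sd / mean)^2)
  tau_eff <- min(tau, sqrt(s2))
  list(meanlog = log(mean) - s2 / 2,
       tau = tau_eff,
       sdlog_resid = sqrt(max(0, s2 - tau_eff^2)))
}

draw_group_traits <- function(config, n) {
  tibble(
    group_index = seq_len(n),
    att = exp(rnorm(n, 0, config$trait_att_sdlog)),
    err = exp(rnorm(n, 0, config$trait_err_sdlog)),
    depth = rnorm(n, 0, config$trait_depth_sd),
    wall = exp(rnorm(n, 0, config$trait_wall_sdlog)),
    cortisol = rnorm(n, 0, 1)
  )
}

#' Simulate one shoal session
#'
#' Runs the collective-motion model for a single group and condition and
#' returns the full subframe-resolution trajectory. Use
#' [trajectory_frames()] to downsample to analysis frames and
#' [derive_behaviour_table()] to score clip-level behaviours.
#'
#' @param config A [simulation_config()].
#' @param group_id Group identifier attached to the outputs.
#' @param condition Condition name; must match a name of `config$theta`.
#' @param seed Optional integer seed.
#' @param traits Optional one-row group-trait tibble (columns `att, err,
#'   depth, wall`); defaults to neutral traits.
#'
#' @return Object of class `shoal_trajectory`: list with `positions` (an
#'   `(n_steps + 1) x (3 n_fish)` matrix of x, y, z coordinate blocks),
#'   `dt`, `group_id`, `condition`, `config`.
#' @export
simulate_shoal <- function(config, group_id, condition, seed = NULL,
                           traits = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!condition %in% names(config$theta)) {
    abort(sprintf("unknown condition '%s'; config defines: %s", condition,
                  paste(names(config$theta), collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(traits)) traits <- list(att = 1, err = 1, depth = 0, wall = 1)
  theta <- config$theta[[condition]]
  tank <- config$tank
  n <- config$n_fish
  dt <- 1 / config$subframes_per_s
  n_steps <- config$n_frames * config$frame_interval_s * config$subframes_per_s

  # release near the tank centre, mid-depth
  init <- cbind(
    pmin(pmax(tank$length_cm / 2 + rnorm(n, 0, 2), 0), tank$length_cm),
    pmin(pmax(tank$width_cm / 2 + rnorm(n, 0, 2), 0), tank$width_cm),
    pmin(pmax(tank$water_depth_cm / 2 + rnorm(n, 0, 2), 0), tank$water_depth_cm)
  )
  pos <- simulate_shoal_core(
    init, n_steps, dt,
    tank$length_cm, tank$width_cm, tank$water_depth_cm,
    theta,
    config$w_att * traits$att, config$kappa,
    config$w_rep, config$rep_radius,
    config$w_wall * traits$wall, config$w_wall_base * traits$wall,
    config$detach_rate, config$return_rate, config$indep_att,
    config$depth_w0 + traits$depth, config$depth_w1,
    config$sigma_xy, config$sigma_z,
    config$p0_err * traits$err, config$beta_err,
    config$burst_speed
  )
  structure(
    list(positions = pos, dt = dt, group_id = group_id, condition = condition,
         config = config),
    class = "shoal_trajectory"
  )
}

#' Downsample a trajectory to analysis frames
#'
#' Retains one position frame every `frame_interval_s` seconds (frame 0 at
#' the start of the session), the sampling scheme of the overhead-camera
#' image extraction.
#'
#' @param traj A `shoal_trajectory` from [simulate_shoal()].
#' @return Long-format tibble: `group_id, condition, frame_index, time_s,
#'   fish_id, x_cm, y_cm, z_cm`.
#' @export
trajectory_frames <- function(traj) {
  stopifnot(inherits(traj, "shoal_trajectory"))
  cfg <- traj$config
  n <- cfg$n_fish
  step <- cfg$frame_interval_s * cfg$subframes_per_s
  rows <- 1L + (seq_len(cfg$n_frames) - 1L) * step
  tibble(
    group_id = traj$group_id,
    condition = traj$condition,
    frame_index = rep(seq_len(cfg$n_frames) - 1L, each = n),
    time_s = rep((seq_len(cfg$n_frames) - 1L) * cfg$frame_interval_s, each = n),
    fish_id = rep(seq_len(n), times = cfg$n_frames),
    x_cm = as.vector(t(traj$positions[rows, 1:n, drop = FALSE])),
    y_cm = as.vector(t(traj$positions[rows, n + 1:n, drop = FALSE])),
    z_cm = as.vector(t(traj$positions[rows, 2 * n + 1:n, drop = FALSE]))
  )
}

#' Score clip-level behaviours from a trajectory
#'
#' Cuts a session into clips of `clip_duration_s` and scores, per clip,
#' presence/absence of the two canonical behaviours: `erratic_movement`
#' (any fish exceeding the speed threshold — or, when enabled, the
#' turning-angle threshold — in any subframe of the clip) and `top_half`
#' (any fish above half the water depth at any subframe).
#'
#' @param traj A `shoal_trajectory`.
#' @param clip_duration_s Clip length, s (default 10).
#' @param speed_threshold_cm_s,turn_threshold_rad Detection thresholds;
#'   defaults from the trajectory's config.
#'
#' @return Behaviour tibble: `group_id, condition, clip_index, behaviour,
#'   present`.
#' @export
derive_behaviour_table <- function(traj, clip_duration_s = 10,
                                   speed_threshold_cm_s = NULL,
                                   turn_threshold_rad = NULL) {
  stopifnot(inherits(traj, "shoal_trajectory"))
  cfg <- traj$config
  speed_threshold_cm_s <- speed_threshold_cm_s %||% cfg$erratic_speed_cm_s
  turn_threshold_rad <- turn_threshold_rad %||% cfg$erratic_turn_rad
  n <- cfg$n_fish
  pos <- traj$positions
  n_steps <- nrow(pos) - 1L
  steps_per_clip <- as.integer(round(clip_duration_s * cfg$subframes_per_s))
  n_clips <- segment_clips(n_steps / cfg$subframes_per_s, clip_duration_s)

  x <- pos[, 1:n, drop = FALSE]
  y <- pos[, n + 1:n, drop = FALSE]
  z <- pos[, 2 * n + 1:n, drop = FALSE]
  dx <- diff(x); dy <- diff(y)
  speed <- sqrt(dx^2 + dy^2) / traj$dt          # n_steps x n_fish
  fast <- speed > speed_threshold_cm_s
  if (is.finite(turn_threshold_rad)) {
    heading <- atan2(dy, dx)
    turn <- abs(diff(heading))
    turn <- pmin(turn, 2 * pi - turn)
    fast[-1, ] <- fast[-1, , drop = FALSE] | (turn > turn_threshold_rad)
  }
  clip_of_step <- rep(seq_len(n_clips), each = steps_per_clip)
  erratic <- as.integer(tapply(rowSums(fast) > 0, clip_of_step, any))
  high <- z[-1, , drop = FALSE] > cfg$tank$water_depth_cm / 2
  top_half <- as.integer(tapply(rowSums(high) > 0, clip_of_step, any))

  tibble(
    group_id = traj$group_id,
    condition = traj$condition,
    clip_index = rep(seq_len(n_clips) - 1L, times = 2),
    behaviour = rep(c("erratic_movement", "top_half"), each = n_clips),
    present = c(erratic, top_half)
  )
}

#' Simulate whole-body cortisol concentrations
#'
#' Draws one cortisol value per group per condition (the one fish sampled
#' and euthanised at the end of each session) from a lognormal calibrated so
#' the per-condition sample mean and SE approximate the configured targets
#' at `n_groups` fish. A shared per-group effect (SD `cortisol_group_tau`
#' on the log scale) makes the repeated-measures structure real.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer seed.
#' @param traits Optional group-trait tibble (uses its `cortisol` column as
#'   the standard-normal group effect); drawn fresh when `NULL`.
#'
#' @return Tibble: `group_id, condition, fish_id, cortisol_ng_per_g`.
#' @export
simulate_cortisol <- function(config, seed = NULL, traits = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_groups
  if (is.null(traits)) traits <- draw_group_traits(config, n)
  conditions <- names(config$theta)
  purrr::map_dfr(conditions, function(cond) {
    par <- cortisol_lognormal_params(config$cortisol_mean[[cond]],
                                     config$cortisol_se[[cond]] * sqrt(n),
                                     config$cortisol_group_tau)
    tibble(
      group_id = group_label(seq_len(n)),
      condition = cond,
      fish_id = paste0("sampled_", cond),
      cortisol_ng_per_g = exp(par$meanlog + par$tau * traits$cortisol +
                                rnorm(n, 0, par$sdlog_resid))
    )
  })
}

group_label <- function(i) sprintf("g%02d", i)

#' Simulate a complete synthetic study
#'
#' Generates everything the analysis pipeline consumes: per-frame fish
#' positions for every group in both conditions, clip-level behaviour
#' tables, per-fish body lengths, and whole-body cortisol concentrations.
#' One master seed deterministically spawns per-group/per-condition child
#' seeds, so any session can be regenerated in isolation.
#'
#' @param config A [simulation_config()].
#' @param seed Master seed (integer).
#'
#' @return Object of class `shoal_study`: list with tibbles `positions`,
#'   `behaviour`, `body_lengths`, `cortisol`, plus `traits`, `config`,
#'   `seed`.
#' @examples
#' study <- simulate_study(simulation_config(n_groups = 2, n_frames = 12), seed = 7)
#' head(study$positions)
#' @export
simulate_study <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  n_g <- config$n_groups
  conditions <- names(config$theta)
  child_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   n_g * length(conditions) + 2L),
                        nrow = n_g + 1L)
  traits <- draw_group_traits(config, n_g)
  body_lengths <- tibble(
    group_id = rep(group_label(seq_len(n_g)), each = config$n_fish),
    fish_id = rep(seq_len(config$n_fish), times = n_g),
    standard_length_mm = pmax(
      rnorm(n_g * config$n_fish, config$body_length_mean_mm,
            config$body_length_sd_mm),
      config$body_length_mean_mm / 4
    )
  )

  positions <- vector("list", n_g * length(conditions))
  behaviour <- vector("list", n_g * length(conditions))
  k <- 0L
  for (g in seq_len(n_g)) {
    for (ci in seq_along(conditions)) {
      k <- k + 1L
      traj <- simulate_shoal(config, group_label(g), conditions[ci],
                             seed = child_seeds[g, ci],
                             traits = traits[g, ])
      positions[[k]] <- trajectory_frames(traj)
      behaviour[[k]] <- derive_behaviour_table(traj)
    }
  }
  cortisol <- simulate_cortisol(config, seed = child_seeds[n_g + 1L, 1L],
                                traits = traits)
  structure(
    list(positions = dplyr::bind_rows(positions),
         behaviour = dplyr::bind_rows(behaviour),
         body_lengths = body_lengths,
         cortisol = cortisol,
         traits = traits,
         config = config,
         seed = seed),
    class = "shoal_study"
  )
}

#' @exportS3Method base::print
print.shoal_study <- function(x, ...) {
  cat(sprintf(
    "<shoal_study> %d groups x %d conditions; %d position rows, %d behaviour rows (seed %d)\n",
    x$config$n_groups, length(x$config$theta),
    nrow(x$positions), nrow(x$behaviour), x$seed
  ))
  invisible(x)
}
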