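#' Trajectory scenario for the synthetic swim generator
#'
#' Describes one simulated larval swim recording in a circular well
#' (24-well format, ~7.8 mm radius) at 30 frames/s. The model is a
#' correlated random walk: per-frame speeds are gamma-distributed with mean
#' `mean_speed` and coefficient of variation `speed_cv`, headings evolve by
#' wrapped-normal increments, a wall-affinity term steers the fish toward
#' tangential swimming near the well periphery (high for controls, which show
#' organized wall-following; low for mutants, which swim irregularly in the
#' interior), brief immobile pauses interrupt swimming, and sustained circling
#' bouts (entered at rate `rotation_bias` per second) produce full rotations.
#' PTZ scenarios multiply speed by a factor that decays exponentially with
#' half-life `ptz_decay_halflife_s`, emulating the waning drug effect.
#'
#' Scenario defaults (speeds, bout rates, affinities) are order-of-magnitude
#' choices typical of 120-hpf larvae; the published source reports these
#' quantities only graphically.
#'
#' @param scenario One of `"control"`, `"napb_cr"`, `"control_ptz"`,
#'   `"napb_cr_ptz"`.
#' @param frame_rate Frames per second (default 30).
#' @param arena_radius Well radius, mm (default 7.8).
#' @param mean_speed Mean swim speed while mobile, mm/s (default 3 control,
#'   6 mutant).
#' @param speed_cv Coefficient of variation of per-frame speed (default 0.6).
#' @param turn_sd_deg SD of the per-frame wrapped-normal heading increment,
#'   degrees (default 25).
#' @param wall_affinity Strength (0-1) of steering toward tangential
#'   wall-following (default 0.8 control, 0.2 mutant).
#' @param rotation_bias Rate of entering a sustained circling bout, per
#'   second (default 0.02 control, 0.15 mutant).
#' @param bout_duration_s Circling-bout length, seconds (default 1.5).
#' @param bout_turn_rate_deg_s Turn rate during a bout, deg/s (default 240,
#'   so one bout completes a full 360-degree rotation).
#' @param pause_rate Rate of entering an immobile pause, per second
#'   (default 0.3 control, 0.1 mutant).
#' @param pause_duration_s Pause length, seconds (default 0.5).
#' @param ptz_speed_multiplier Initial speed multiplier under PTZ
#'   (default 2.5; 1 outside PTZ scenarios).
#' @param ptz_decay_halflife_s Half-life of the PTZ speed effect, seconds
#'   (default 300).
#' @param phase_schedule Tibble with columns `phase` (`"dark"`/`"light"`) and
#'   `duration_s`; default 300 s dark acclimation followed by six alternating
#'   120-s bins starting with light (the dark-to-light protocol).
#' @param seed Integer seed; identical scenario + seed gives a bit-identical
#'   trajectory.
#' @return An object of class `trajectory_scenario`.
#' @export
trajectory_scenario <- function(scenario = c("control", "napb_cr",
                                             "control_ptz", "napb_cr_ptz"),
                                frame_rate = 30,
                                arena_radius = 7.8,
                                mean_speed = NULL,
                                speed_cv = 0.6,
                                turn_sd_deg = 25,
                                wall_affinity = NULL,
                                rotation_bias = NULL,
                                bout_duration_s = 1.5,
                                bout_turn_rate_deg_s = 240,
                                pause_rate = NULL,
                                pause_duration_s = 0.5,
                                ptz_speed_multiplier = 2.5,
                                ptz_decay_halflife_s = 300,
                                phase_schedule = NULL,
                                seed = NULL) {
  scenario <- match.arg(scenario)
  is_ptz <- grepl("_ptz$", scenario)
  is_mutant <- grepl("^napb_cr", scenario)
  check_number(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  check_number(arena_radius, "arena_radius", lower = 0, strict_lower = TRUE)
  if (is.null(mean_speed)) mean_speed <- if (is_mutant) 6 else 3
  check_number(mean_speed, "mean_speed", lower = 0)
  if (is.null(wall_affinity)) wall_affinity <- if (is_mutant) 0.2 else 0.8
  if (is.null(rotation_bias)) rotation_bias <- if (is_mutant) 0.15 else 0.02
  if (is.null(pause_rate)) pause_rate <- if (is_mutant) 0.1 else 0.3
  if (is.null(phase_schedule)) {
    phase_schedule <- tibble(
      phase = c("dark", rep(c("light", "dark"), 3)),
      duration_s = c(300, rep(120, 6)))
  }
  stopifnot(all(c("phase", "duration_s") %in% names(phase_schedule)),
            all(phase_schedule$duration_s > 0))
  structure(
    list(scenario = scenario, frame_rate = frame_rate,
         arena_radius = arena_radius, mean_speed = mean_speed,
         speed_cv = speed_cv, turn_sd_deg = turn_sd_deg,
         wall_affinity = wall_affinity, rotation_bias = rotation_bias,
         bout_duration_s = bout_duration_s,
         bout_turn_rate_deg_s = bout_turn_rate_deg_s,
         pause_rate = pause_rate, pause_duration_s = pause_duration_s,
         ptz_speed_multiplier = if (is_ptz) ptz_speed_multiplier else 1,
         ptz_decay_halflife_s = ptz_decay_halflife_s,
         phase_schedule = as_tibble(phase_schedule),
         seed = seed),
    class = "trajectory_scenario"
  )
}

#' Simulate a larval swim trajectory with known ground truth
#'
#' Runs the correlated random walk described in [trajectory_scenario()].
#' Wall handling is specular reflection with a final clamp, so every position
#' satisfies `sqrt(x^2 + y^2) <= arena_radius`. Ground truth is computed from
#' the emitted positions themselves (path length, mean speed, rotation-bout
#' count, mobile-time fraction at a 0.5 mm/s speed threshold), so downstream
#' metrics can be checked for exact recovery.
#'
#' @param scenario A [trajectory_scenario()].
#' @return A list with elements
#'   \describe{
#'     \item{trajectory}{`mea_trajectory` tibble: `time_s`, `x_mm`, `y_mm`,
#'       `phase`, with attributes `arena_radius` and `frame_rate`.}
#'     \item{truth}{list: `path_length_mm`, `mean_speed_mm_s`,
#'       `n_rotation_bouts`, `mobile_fraction`.}
#'   }
#' @export
simulate_trajectory <- function(scenario) {
  stopifnot(inherits(scenario, "trajectory_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    fr <- sc$frame_rate
    dt <- 1 / fr
    total_s <- sum(sc$phase_schedule$duration_s)
    n <- round(total_s * fr)
    times <- seq(0, n - 1) / fr
    phase_edges <- cumsum(sc$phase_schedule$duration_s)
    phase <- sc$phase_schedule$phase[findInterval(times, c(0, phase_edges))]

    R <- sc$arena_radius
    # pre-draw all randomness so the per-frame loop is cheap
    turn_inc <- rnorm(n, 0, sc$turn_sd_deg * pi / 180)
    if (sc$mean_speed > 0) {
      shp <- 1 / sc$speed_cv^2
      speed_draw <- rgamma(n, shape = shp, scale = sc$mean_speed / shp)
    } else speed_draw <- rep(0, n)
    u_bout <- runif(n)
    u_pause <- runif(n)
    bout_dir <- sample(c(-1, 1), n, replace = TRUE)
    decay <- if (sc$ptz_speed_multiplier != 1) {
      1 + (sc$ptz_speed_multiplier - 1) * 2^(-times / sc$ptz_decay_halflife_s)
    } else rep(1, n)

    p_bout <- sc$rotation_bias * dt
    p_pause <- sc$pause_rate * dt
    bout_frames <- round(sc$bout_duration_s * fr)
    pause_frames <- round(sc$pause_duration_s * fr)
    bout_turn <- sc$bout_turn_rate_deg_s * pi / 180 * dt

    x <- numeric(n); y <- numeric(n)
    # start at mid-radius with a random heading
    th0 <- runif(1, 0, 2 * pi)
    x[1] <- 0.5 * R * cos(th0); y[1] <- 0.5 * R * sin(th0)
    heading <- runif(1, 0, 2 * pi)
    circ_dir <- sample(c(-1, 1), 1)   # persistent wall-circulation direction
    bout_left <- 0L; pause_left <- 0L; dir_now <- 1
    n_bouts <- 0L
    speeds <- numeric(n); speeds[1] <- 0

    for (i in 2:n) {
      if (pause_left > 0L) {
        pause_left <- pause_left - 1L
        x[i] <- x[i - 1]; y[i] <- y[i - 1]; speeds[i] <- 0
        next
      }
      if (bout_left > 0L) {
        bout_left <- bout_left - 1L
        heading <- heading + dir_now * bout_turn
      } else {
        if (u_bout[i] < p_bout) {
          bout_left <- bout_frames
          dir_now <- bout_dir[i]
          n_bouts <- n_bouts + 1L
        } else if (u_pause[i] < p_pause) {
          pause_left <- pause_frames
          x[i] <- x[i - 1]; y[i] <- y[i - 1]; speeds[i] <- 0
          next
        }
        heading <- heading + turn_inc[i]
        r <- sqrt(x[i - 1]^2 + y[i - 1]^2)
        if (sc$wall_affinity > 0 && r > 0.05 * R) {
          # steer toward tangential travel at ~0.9R, weighted by proximity
          phi <- atan2(y[i - 1], x[i - 1])
          target <- phi + circ_dir * pi / 2 - circ_dir * 1.2 * (0.9 - r / R)
          d <- (target - heading) %% (2 * pi)
          if (d > pi) d <- d - 2 * pi
          heading <- heading + sc$wall_affinity * (r / R)^2 * d
        }
      }
      sp <- speed_draw[i] * decay[i]
      step <- sp * dt
      xn <- x[i - 1] + step * cos(heading)
      yn <- y[i - 1] + step * sin(heading)
      rn <- sqrt(xn^2 + yn^2)
      if (rn > R) {
        # specular reflection about the radial normal at the old position
        r0 <- sqrt(x[i - 1]^2 + y[i - 1]^2)
        nx <- if (r0 > 0) x[i - 1] / r0 else cos(heading)
        ny <- if (r0 > 0) y[i - 1] / r0 else sin(heading)
        vx <- cos(heading); vy <- sin(heading)
        dot <- vx * nx + vy * ny
        vx <- vx - 2 * dot * nx; vy <- vy - 2 * dot * ny
        heading <- atan2(vy, vx)
        xn <- x[i - 1] + step * vx
        yn <- y[i - 1] + step * vy
        rn <- sqrt(xn^2 + yn^2)
        if (rn > R) { xn <- xn * R / rn * 0.999; yn <- yn * R / rn * 0.999 }
      }
      x[i] <- xn; y[i] <- yn
      speeds[i] <- sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2) / dt
    }

    traj <- new_mea_trajectory(
      tibble(time_s = times, x_mm = x, y_mm = y, phase = phase),
      arena_radius = R, frame_rate = fr)
    path <- sum(sqrt(diff(x)^2 + diff(y)^2))
    list(trajectory = traj,
         truth = list(path_length_mm = path,
                      mean_speed_mm_s = path / (times[n] - times[1]),
                      n_rotation_bouts = n_bouts,
                      mobile_fraction = mean(speeds[-1] > 0.5)))
  })
}

new_mea_trajectory <- function(df, arena_radius = NA_real_,
                               frame_rate = NA_real_) {
  out <- as_tibble(df)
  attr(out, "arena_radius") <- arena_radius
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("mea_trajectory", class(out))
  out
}
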