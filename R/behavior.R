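check_trajectory <- function(traj, min_rows = 2) {
  stopifnot(is.data.frame(traj),
            all(c("time_s", "x_mm", "y_mm") %in% names(traj)))
  if (nrow(traj) < min_rows)
    abort(sprintf("trajectory needs at least %d samples.", min_rows))
  if (is.unsorted(traj$time_s, strictly = TRUE))
    abort("trajectory times must be strictly increasing.")
  if (!all(is.finite(traj$x_mm)) || !all(is.finite(traj$y_mm)))
    abort("trajectory coordinates must be finite.")
  invisible(traj)
}

#' Total distance travelled
#'
#' Sum of successive Euclidean displacements. `min_displacement_mm` is an
#' optional tracking-jitter filter (displacements below it contribute 0);
#' it is off by default.
#'
#' @param traj Trajectory data frame with `time_s`, `x_mm`, `y_mm`.
#' @param min_displacement_mm Jitter filter threshold, mm (default 0 = off).
#' @return Distance in mm.
#' @export
total_distance <- function(traj, min_displacement_mm = 0) {
  check_trajectory(traj)
  d <- sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2)
  if (min_displacement_mm > 0) d[d < min_displacement_mm] <- 0
  sum(d)
}

#' Mean swim velocity
#'
#' Total distance divided by elapsed time.
#'
#' @inheritParams total_distance
#' @return Velocity in mm/s.
#' @export
mean_velocity <- function(traj, min_displacement_mm = 0) {
  check_trajectory(traj)
  total_distance(traj, min_displacement_mm) /
    (traj$time_s[nrow(traj)] - traj$time_s[1])
}

wrap_deg <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

#' Count rotation events
#'
#' Counts clockwise and counterclockwise rotations from a centroid track.
#' Points are first thinned by the minimum-displacement filter: a point is
#' accepted only when it lies at least `min_step_mm` from the last accepted
#' point. Headings are the directions between successive accepted points;
#' signed heading changes accumulate, a full `full_turn_deg` of cumulative
#' same-direction turning counts one rotation (the accumulator keeps the
#' remainder), and a counter-turn exceeding `opposing_tolerance_deg` resets
#' the accumulator to the counter-turn without counting. Counterclockwise
#' (mathematically positive) turning is reported as `ccw`.
#'
#' @param traj Trajectory data frame with `time_s`, `x_mm`, `y_mm`.
#' @param spec A [rotation_spec()].
#' @return One-row tibble `cw`, `ccw` (integer counts).
#' @export
count_rotations <- function(traj, spec = rotation_spec()) {
  check_trajectory(traj, min_rows = 3)
  x <- traj$x_mm; y <- traj$y_mm
  # minimum-displacement thinning
  acc_x <- x[1]; acc_y <- y[1]
  keep <- 1L
  for (i in 2:length(x)) {
    if (sqrt((x[i] - acc_x)^2 + (y[i] - acc_y)^2) >= spec$min_step_mm) {
      keep <- c(keep, i)
      acc_x <- x[i]; acc_y <- y[i]
    }
  }
  if (length(keep) < 3) {
    warn("fewer than 3 points pass the minimum-displacement filter; no rotations counted.")
    return(tibble(cw = 0L, ccw = 0L))
  }
  hx <- x[keep]; hy <- y[keep]
  headings <- atan2(diff(hy), diff(hx)) * 180 / pi
  dh <- wrap_deg(diff(headings))
  acc <- 0
  cw <- 0L; ccw <- 0L
  for (d in dh) {
    if (acc != 0 && sign(d) != 0 && sign(d) != sign(acc) &&
        abs(d) > spec$opposing_tolerance_deg) {
      acc <- d
    } else {
      acc <- acc + d
    }
    if (acc >= spec$full_turn_deg) {
      ccw <- ccw + 1L
      acc <- acc - spec$full_turn_deg
    } else if (acc <= -spec$full_turn_deg) {
      cw <- cw + 1L
      acc <- acc + spec$full_turn_deg
    }
  }
  tibble(cw = cw, ccw = ccw)
}

#' Mobile and immobile time
#'
#' Per-frame speed is compared with a threshold; interval durations are summed
#' into mobile and immobile time, which add up to the analyzed duration. The
#' default threshold of 0.5 mm/s is a package convention: the acquisition
#' software's pixel-change "mobility" measure is not reproducible from a
#' centroid track.
#'
#' @param traj Trajectory data frame with `time_s`, `x_mm`, `y_mm`.
#' @param speed_threshold_mm_s Speed above which a frame interval counts as
#'   mobile (default 0.5).
#' @return One-row tibble `mobile_s`, `immobile_s`.
#' @export
mobility <- function(traj, speed_threshold_mm_s = 0.5) {
  check_trajectory(traj)
  check_number(speed_threshold_mm_s, "speed_threshold_mm_s", lower = 0,
               strict_lower = TRUE)
  dt <- diff(traj$time_s)
  sp <- sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2) / dt
  mobile <- sp > speed_threshold_mm_s
  tibble(mobile_s = sum(dt[mobile]), immobile_s = sum(dt[!mobile]))
}

#' Per-bin behavioral metrics across the light-phase schedule
#'
#' Cuts the trajectory into consecutive bins of `bin_s` seconds (default
#' 120 s, the dark/light cycle length) starting at `start_s`, and computes
#' distance, velocity, rotations and mobility independently per bin. Each bin
#' is labelled with its phase (the phase of most of its samples). Bins tile
#' the analyzed span, so bin distances sum to the total distance over it.
#'
#' @param traj Trajectory data frame with `time_s`, `x_mm`, `y_mm` and
#'   optionally `phase`.
#' @param bin_s Bin length in seconds (default 120).
#' @param start_s Start of the analyzed span (default 0); use this to skip a
#'   dark-acclimation period.
#' @param rotation_spec A [rotation_spec()].
#' @param speed_threshold_mm_s Mobility threshold (default 0.5 mm/s).
#' @return Tibble with one row per bin: `bin`, `t0`, `t1`, `phase`,
#'   `distance_mm`, `velocity_mm_s`, `cw`, `ccw`, `mobile_s`, `immobile_s`.
#' @export
bin_by_phase <- function(traj, bin_s = 120, start_s = 0,
                         rotation_spec = meafish::rotation_spec(),
                         speed_threshold_mm_s = 0.5) {
  check_trajectory(traj)
  check_number(bin_s, "bin_s", lower = 0, strict_lower = TRUE)
  t_end <- traj$time_s[nrow(traj)]
  if (start_s >= t_end) abort("`start_s` is beyond the trajectory.")
  edges <- seq(start_s, t_end, by = bin_s)
  if (edges[length(edges)] < t_end - 1e-9)
    edges <- c(edges, t_end)
  n_bins <- length(edges) - 1
  rows <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    # include the edge sample so consecutive bins share their boundary point
    # and displacements tile the full span
    in_bin <- traj$time_s >= edges[b] - 1e-9 & traj$time_s <= edges[b + 1] + 1e-9
    sub <- traj[in_bin, , drop = FALSE]
    if (nrow(sub) < 2) next
    ph <- if ("phase" %in% names(sub)) names(which.max(table(sub$phase)))
          else NA_character_
    rot <- if (nrow(sub) >= 3) count_rotations(sub, rotation_spec)
           else tibble(cw = 0L, ccw = 0L)
    mob <- mobility(sub, speed_threshold_mm_s)
    rows[[b]] <- tibble(
      bin = b, t0 = edges[b], t1 = edges[b + 1], phase = ph,
      distance_mm = total_distance(sub),
      velocity_mm_s = mean_velocity(sub),
      cw = rot$cw, ccw = rot$ccw,
      mobile_s = mob$mobile_s, immobile_s = mob$immobile_s)
  }
  bind_rows(rows)
}

#' Full behavioral report for one trajectory
#'
#' Whole-track totals plus the per-bin table from [bin_by_phase()].
#'
#' @inheritParams bin_by_phase
#' @return One-row tibble: `total_distance_mm`, `mean_velocity_mm_s`, `cw`,
#'   `ccw`, `mobile_s`, `immobile_s`, with the per-bin table attached as the
#'   attribute `bins`.
#' @export
behavior_metrics <- function(traj, bin_s = 120, start_s = 0,
                             rotation_spec = meafish::rotation_spec(),
                             speed_threshold_mm_s = 0.5) {
  check_trajectory(traj, min_rows = 3)
  sub <- traj[traj$time_s >= start_s - 1e-9, , drop = FALSE]
  rot <- count_rotations(sub, rotation_spec)
  mob <- mobility(sub, speed_threshold_mm_s)
  out <- tibble(
    total_distance_mm = total_distance(sub),
    mean_velocity_mm_s = mean_velocity(sub),
    cw = rot$cw, ccw = rot$ccw,
    mobile_s = mob$mobile_s, immobile_s = mob$immobile_s)
  attr(out, "bins") <- bin_by_phase(sub, bin_s, start_s = sub$time_s[1],
                                    rotation_spec = rotation_spec,
                                    speed_threshold_mm_s = speed_threshold_mm_s)
  out
}
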