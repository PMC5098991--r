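#' Body-oscillation heading signal of the replica
#'
#' The replica's heading relative to the tank length (x-axis) oscillates at
#' 2 Hz with a 10 degree peak-to-peak amplitude around a mean of 45 degrees
#' when the replica moves toward increasing y (facing the tank centre from
#' one side) or 135 degrees when moving toward decreasing y.
#'
#' @param t Time (s), vector.
#' @param vy_sign +1 or -1: direction of motion along the tank width.
#' @param freq_hz Oscillation frequency (Hz), default 2.
#' @param peak_to_peak_deg Peak-to-peak amplitude (degrees), default 10.
#' @return Heading in degrees, same length as `t`.
#' @examples
#' mean(heading_signal(seq(0, 1, by = 1/30)[1:30], +1))  # 45
#' @export
heading_signal <- function(t, vy_sign = +1, freq_hz = 2, peak_to_peak_deg = 10) {
  stopifnot(vy_sign %in% c(-1, 1))
  base <- if (vy_sign > 0) 45 else 135
  base + (peak_to_peak_deg / 2) * sin(2 * pi * freq_hz * t)
}

#' Build a replica waypoint program from a source trajectory
#'
#' Downsamples a uniformly sampled source trajectory to waypoints every
#' `interval` seconds (default 2.5 s), then reconstructs the commanded
#' replica motion by piecewise-linear interpolation between waypoints at the
#' source frame rate, attaching the 2 Hz body-oscillation heading signal
#' whose mean (45 or 135 degrees) tracks the sign of the y-velocity between
#' waypoints.
#'
#' The waypoint count is `floor(duration / interval) + 1` with
#' `duration = n / fps`; a final waypoint time that falls less than one
#' frame period beyond the last sample reuses the last sample.
#'
#' @param source A [trajectory3d()], uniformly sampled.
#' @param interval Waypoint spacing (s), default 2.5.
#' @return Object of class `replica_program`: list with `waypoints`
#'   (data.frame `t_s`, `x_cm`, `y_cm`, `z_cm`), `trajectory` (a
#'   [trajectory3d()] with a `heading_deg` column) and `interval_s`.
#' @export
make_replica_program <- function(source, interval = 2.5) {
  stopifnot(inherits(source, "trajectory3d"), interval > 0)
  fps <- traj_fps(source)
  n <- nrow(source)
  duration <- n / fps
  if (duration < 2 * interval)
    stop("source must cover at least two waypoint intervals")
  dts <- diff(source$t_s)
  if (length(dts) && max(abs(dts - 1 / fps)) > 1e-9)
    stop("source trajectory is not uniformly sampled")
  wp_t <- seq(0, duration, by = interval)
  wp_t <- wp_t[wp_t <= duration + 1e-9]
  samp <- function(v) stats::approx(source$t_s, v, xout = wp_t, rule = 2)$y
  wp <- data.frame(t_s = wp_t, x_cm = samp(source$x_cm),
                   y_cm = samp(source$y_cm), z_cm = samp(source$z_cm))
  # commanded motion: linear between waypoints, at the source frame rate
  t_out <- seq(0, wp_t[length(wp_t)], by = 1 / fps)
  interp <- function(v) stats::approx(wp_t, v, xout = t_out)$y
  x <- interp(wp$x_cm); y <- interp(wp$y_cm); z <- interp(wp$z_cm)
  # direction of travel along y within each waypoint leg (ties -> +1)
  leg <- pmin(findInterval(t_out, wp_t), length(wp_t) - 1)
  dy <- wp$y_cm[leg + 1] - wp$y_cm[leg]
  vy_sign <- ifelse(dy < 0, -1, 1)
  heading <- ifelse(vy_sign > 0, 45, 135) +
    5 * sin(2 * pi * 2 * t_out)
  traj <- trajectory3d(x, y, z, fps = fps, provenance = "simulated",
                       heading_deg = heading)
  structure(list(waypoints = wp, trajectory = traj, interval_s = interval,
                 fps = fps),
            class = "replica_program")
}

#' @export
print.replica_program <- function(x, ...) {
  cat(sprintf("Replica program: %d waypoints every %g s (%.1f s at %g fps)\n",
              nrow(x$waypoints), x$interval_s,
              nrow(x$trajectory) / x$fps, x$fps))
  invisible(x)
}

#' Restrict a replica program to planar motion at a fixed depth
#'
#' Blocks the z-axis of the program at `depth_cm` below the water surface
#' (mid water column by default), leaving x, y and heading untouched. Used
#' for the planar-motion control condition.
#'
#' @param program A [make_replica_program()] result.
#' @param depth_cm Fixed depth (cm), default 7.5.
#' @param water_depth_cm Water depth (cm) used to validate `depth_cm`.
#' @return A `replica_program` with constant z. Idempotent.
#' @export
project_rm2d <- function(program, depth_cm = 7.5, water_depth_cm = 15) {
  stopifnot(inherits(program, "replica_program"))
  if (depth_cm < 0 || depth_cm > water_depth_cm)
    stop("projection depth outside the water column")
  program$waypoints$z_cm <- depth_cm
  program$trajectory$z_cm <- depth_cm
  program
}

#' Simulate a coupled fish-stimulus pair of width-coordinate series
#'
#' Validation harness for directional-information recovery: the stimulus is
#' an autonomous reflected random walk on `[0, width_cm]` and the fish
#' series relaxes toward the stimulus with strength `c` at lag `lag`
#' frames: `fish[t] = (1 - c) * (fish[t-1] + noise) + c * stim[t - lag]`,
#' clamped to the tank width. With `c = 0` the two series are independent;
#' increasing `c` increases the information flowing stimulus -> fish while
#' none flows back.
#'
#' @param c_strength Coupling strength in `[0, 1]`.
#' @param lag Coupling lag (frames, >= 1).
#' @param noise_cm Innovation scale of the fish series (cm).
#' @param length Series length (frames); must exceed `lag`.
#' @param width_cm Tank width (cm), default 30.
#' @param stim_step_cm Innovation scale of the stimulus walk (cm).
#' @param seed Optional integer seed.
#' @return List with numeric vectors `fish_y` and `stim_y`.
#' @export
simulate_coupled_pair <- function(c_strength, lag = 1, noise_cm = 1,
                                  length = 3000, width_cm = 30,
                                  stim_step_cm = 1.5, seed = NULL) {
  stopifnot(c_strength >= 0, c_strength <= 1, lag >= 1, length > lag)
  if (!is.null(seed)) set.seed(seed)
  stim <- numeric(length)
  stim[1] <- width_cm / 2
  steps <- stats::rnorm(length, 0, stim_step_cm)
  for (t in 2:length) stim[t] <- reflect1(stim[t - 1] + steps[t], 0, width_cm)
  fish <- numeric(length)
  fish[1] <- width_cm / 2
  eps <- stats::rnorm(length, 0, noise_cm)
  for (t in 2:length) {
    drive <- if (t - lag >= 1) stim[t - lag] else width_cm / 2
    fish[t] <- (1 - c_strength) * (fish[t - 1] + eps[t]) + c_strength * drive
    fish[t] <- min(max(fish[t], 0), width_cm)
  }
  list(fish_y = fish, stim_y = stim)
}
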