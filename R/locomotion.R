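#' Parameters of the mode-switching locomotion generator
#'
#' The synthetic fish alternates between a baseline `cruise` mode and four
#' event modes taken from the zebrafish ethogram reproduced by the replica:
#' `freezing` (immobility), `thrashing` (rapid oscillation against the
#' partition wall), `erratic` (fast, strongly turning darts) and `diving`
#' (a sustained downward-then-upward excursion along the water column).
#' Mode dwell times are exponential with the given exit rates, so the mean
#' dwell of a mode is `1 / rate` seconds. From `cruise` the next event mode
#' is drawn from `event_weights`; every event mode returns to `cruise`.
#'
#' Per-frame speeds are drawn as `max(0, rnorm(speed_mean, speed_sd))` for
#' the active mode; headings follow a Brownian walk with the mode's turning
#' scale. The protocol-level default cruise speed matches the replica program's
#' 1.69 cm/s average; event-mode magnitudes are generator assumptions (the
#' source protocol describes the repertoire only verbally) and are exposed
#' here rather than hidden.
#'
#' @param dwell_rates Named exit rates (1/s) for the five modes.
#' @param speed_mean,speed_sd Named per-mode speed distributions (cm/s).
#' @param turn_sd Named per-mode heading diffusion (rad / sqrt(s)).
#' @param event_weights Sampling weights of the four event modes when
#'   leaving `cruise`.
#' @param wall_repulsion_cm Range (cm) of the soft inward steering near
#'   walls.
#' @param fps Frame rate (frames per second).
#' @return An object of class `locomotion_params`.
#' @export
locomotion_params <- function(
    dwell_rates = c(cruise = 1 / 8, freezing = 1 / 3, thrashing = 1 / 2,
                    erratic = 1 / 2, diving = 1 / 3),
    speed_mean = c(cruise = 1.69, freezing = 0, thrashing = 4,
                   erratic = 6, diving = 3),
    speed_sd = c(cruise = 0.5, freezing = 0, thrashing = 1.5,
                 erratic = 2, diving = 1),
    turn_sd = c(cruise = 0.25, freezing = 0, thrashing = 6,
                erratic = 4, diving = 0.5),
    event_weights = c(freezing = 1, thrashing = 1, erratic = 1, diving = 1),
    wall_repulsion_cm = 2,
    fps = 30) {
  modes <- c("cruise", "freezing", "thrashing", "erratic", "diving")
  for (v in list(dwell_rates, speed_mean, speed_sd, turn_sd))
    stopifnot(all(modes %in% names(v)))
  stopifnot(all(dwell_rates >= 0), all(speed_mean >= 0), all(speed_sd >= 0),
            fps > 0, wall_repulsion_cm >= 0)
  structure(list(dwell_rates = dwell_rates[modes],
                 speed_mean = speed_mean[modes], speed_sd = speed_sd[modes],
                 turn_sd = turn_sd[modes],
                 event_weights = event_weights,
                 wall_repulsion_cm = wall_repulsion_cm, fps = fps,
                 modes = modes),
            class = "locomotion_params")
}

#' Cruise-only locomotion at a fixed speed
#'
#' Convenience constructor: no event modes, deterministic per-frame speed.
#' Useful for kinematic calibration (the trajectory's raw step speed is
#' exactly `speed`).
#'
#' @param speed Fixed swimming speed (cm/s).
#' @param turn_sd Heading diffusion (rad / sqrt(s)).
#' @param fps Frame rate.
#' @export
cruise_params <- function(speed = 1.69, turn_sd = 0.25, fps = 30) {
  locomotion_params(
    dwell_rates = c(cruise = 0, freezing = 0, thrashing = 0, erratic = 0,
                    diving = 0),
    speed_mean = c(cruise = speed, freezing = 0, thrashing = 0, erratic = 0,
                   diving = 0),
    speed_sd = c(cruise = 0, freezing = 0, thrashing = 0, erratic = 0,
                 diving = 0),
    turn_sd = c(cruise = turn_sd, freezing = 0, thrashing = 0, erratic = 0,
                diving = 0),
    fps = fps)
}

#' Simulate the mode sequence of the locomotion generator
#'
#' Draws alternating cruise / event bouts with exponential dwell times until
#' `duration` seconds are covered, then rasterizes to per-frame labels.
#'
#' @param params A [locomotion_params()].
#' @param duration Simulated time (s).
#' @param seed Optional integer seed.
#' @return List with `bouts` (data.frame: mode, start_s, dur_s) and
#'   `frame_modes` (factor, one label per frame).
#' @export
simulate_mode_sequence <- function(params, duration, seed = NULL) {
  stopifnot(inherits(params, "locomotion_params"), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  rates <- params$dwell_rates
  ew <- params$event_weights
  mode <- "cruise"
  t0 <- 0
  modes <- character(0); starts <- numeric(0); durs <- numeric(0)
  while (t0 < duration) {
    r <- rates[[mode]]
    d <- if (r > 0) stats::rexp(1, r) else duration - t0
    d <- min(d, duration - t0)
    modes <- c(modes, mode); starts <- c(starts, t0); durs <- c(durs, d)
    t0 <- t0 + d
    mode <- if (mode == "cruise") {
      sample(names(ew), 1, prob = ew)
    } else "cruise"
  }
  n <- round(duration * params$fps)
  t_frames <- (seq_len(n) - 1) / params$fps
  idx <- findInterval(t_frames, starts)
  list(bouts = data.frame(mode = modes, start_s = starts, dur_s = durs),
       frame_modes = factor(modes[idx], levels = params$modes))
}

# Reflect a proposed 1-D move off the interval [lo, hi]; preserves the
# step length of the component.
reflect1 <- function(v, lo, hi) {
  span <- hi - lo
  for (i in 1:8) {
    below <- v < lo; v[below] <- 2 * lo - v[below]
    above <- v > hi; v[above] <- 2 * hi - v[above]
    if (!any(v < lo | v > hi)) break
  }
  pmin(pmax(v, lo), hi)
}

#' Simulate a focal fish trajectory in a tank compartment
#'
#' Mode-switching three-dimensional random walk: Brownian heading in the
#' horizontal plane with mode-specific turning scale, a small pitch walk
#' vertically, exponential mode dwell times, soft inward steering within the
#' wall-repulsion range and reflective walls (reflection preserves the step
#' length, so per-frame speed is exactly the drawn speed). Diving bouts
#' force a downward pitch for the first half of the bout and an upward pitch
#' for the second; thrashing steers toward the stimulus-side partition with
#' violent heading reversals.
#'
#' @param params A [locomotion_params()].
#' @param duration Simulated duration (s).
#' @param geometry A [tank_geometry()].
#' @param compartment Compartment the fish is confined to.
#' @param seed Optional integer seed (reproducibility contract: same params
#'   and seed give an identical trajectory).
#' @param start Optional c(x, y, z) start position (cm); defaults to the
#'   compartment centre at mid water column.
#' @return A [trajectory3d()] with a `mode` ground-truth column.
#' @export
simulate_fish <- function(params, duration, geometry,
                          compartment = "central", seed = NULL, start = NULL) {
  stopifnot(inherits(params, "locomotion_params"),
            inherits(geometry, "tank_geometry"), duration > 0)
  xb <- compartment_bounds(geometry, compartment)
  if (diff(xb) <= 2 * params$wall_repulsion_cm ||
      geometry$width_cm <= 2 * params$wall_repulsion_cm)
    stop("compartment smaller than twice the wall-repulsion range")
  if (!is.null(seed)) set.seed(seed)
  ms <- simulate_mode_sequence(params, duration, seed = NULL)
  mode <- as.character(ms$frame_modes)
  n <- length(mode)
  fps <- params$fps; dt <- 1 / fps
  sp <- pmax(0, stats::rnorm(n, params$speed_mean[mode], params$speed_sd[mode]))
  dphi <- stats::rnorm(n, 0, params$turn_sd[mode] * sqrt(dt))
  dpitch <- stats::rnorm(n, 0, 0.15 * sqrt(dt))
  # dive phase: fraction elapsed within the current bout
  bout_id <- cumsum(c(TRUE, mode[-1] != mode[-n]))
  bout_pos <- stats::ave(seq_len(n), bout_id, FUN = function(i) {
    (seq_along(i) - 0.5) / length(i)
  })
  if (is.null(start))
    start <- c(mean(xb), geometry$width_cm / 2, geometry$water_depth_cm / 2)
  x <- y <- z <- numeric(n)
  x[1] <- start[1]; y[1] <- start[2]; z[1] <- start[3]
  phi <- stats::runif(1, 0, 2 * pi)
  pitch <- 0
  rep_range <- params$wall_repulsion_cm
  wall_x <- if (stimulus_compartment(geometry) == "left") xb[1] else xb[2]
  zb <- c(0, geometry$water_depth_cm)
  for (i in seq_len(n)[-1]) {
    m <- mode[i]
    phi <- phi + dphi[i]
    pitch <- 0.9 * pitch + dpitch[i]
    if (m == "thrashing") {
      # whip back and forth while pressed against the partition
      phi <- atan2(0, wall_x - x[i - 1]) +
        (if (i %% 2 == 0) 1 else -1) * stats::runif(1, 0.5, 1.2)
      pitch <- 0.2 * pitch
    } else if (m == "diving") {
      pitch <- if (bout_pos[i] < 0.5) 0.9 else -0.9
    } else {
      pitch <- max(min(pitch, 0.5), -0.5)
    }
    # soft inward steering near walls: rotate the heading toward the interior
    ux <- cos(phi) * cos(pitch); uy <- sin(phi) * cos(pitch)
    push_x <- (x[i - 1] < xb[1] + rep_range) * 1 - (x[i - 1] > xb[2] - rep_range) * 1
    push_y <- (y[i - 1] < rep_range) * 1 -
      (y[i - 1] > geometry$width_cm - rep_range) * 1
    if ((push_x != 0 || push_y != 0) && m != "thrashing") {
      vx <- ux + 0.5 * push_x; vy <- uy + 0.5 * push_y
      phi <- atan2(vy, vx)
      ux <- cos(phi) * cos(pitch); uy <- sin(phi) * cos(pitch)
    }
    step <- sp[i] * dt
    x[i] <- reflect1(x[i - 1] + step * ux, xb[1], xb[2])
    y[i] <- reflect1(y[i - 1] + step * uy, 0, geometry$width_cm)
    z[i] <- reflect1(z[i - 1] + step * sin(pitch), zb[1], zb[2])
  }
  trajectory3d(x, y, z, fps = fps, provenance = "simulated", mode = mode)
}
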