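#' Speed and acceleration from a 3D trajectory
#'
#' Velocity is the first difference of position times the frame rate,
#' smoothed per axis with a centred moving average (default 18 frames);
#' speed is the Euclidean norm of the smoothed velocity. Acceleration is
#' the norm of the first difference of the smoothed velocity vector times
#' the frame rate.
#'
#' @param traj A [trajectory3d()].
#' @param smooth_window Moving-average window (frames), default 18.
#' @return List with `speed` (length `n - 1`, cm/s) and `acceleration`
#'   (length `n - 2`, cm/s^2).
#' @export
kinematics <- function(traj, smooth_window = 18) {
  stopifnot(inherits(traj, "trajectory3d"), nrow(traj) >= 3)
  fps <- traj_fps(traj)
  if (max(abs(diff(traj$t_s) - 1 / fps)) > 1e-9)
    stop("trajectory time base is not uniform")
  vx <- diff(traj$x_cm) * fps
  vy <- diff(traj$y_cm) * fps
  vz <- diff(traj$z_cm) * fps
  w <- min(smooth_window, length(vx))
  vx <- smooth_ma(vx, w); vy <- smooth_ma(vy, w); vz <- smooth_ma(vz, w)
  speed <- sqrt(vx^2 + vy^2 + vz^2)
  ax <- diff(vx) * fps; ay <- diff(vy) * fps; az <- diff(vz) * fps
  list(speed = speed, acceleration = sqrt(ax^2 + ay^2 + az^2))
}

#' Time budgets over the virtual tank sections and water-column levels
#'
#' Classifies every frame into the three equal length sections of the
#' central compartment (relative to the stimulus side) and the three equal
#' water-column levels, and converts frame counts to seconds.
#'
#' @param traj A [trajectory3d()] of the focal fish.
#' @param geometry A [tank_geometry()].
#' @return List with `T_N`, `T_mid_len`, `T_F`, `T_outside` (s, length
#'   axis), `T_T`, `T_mid_depth`, `T_B` (s, depth axis) and `analysed_s`.
#' @export
time_budgets <- function(traj, geometry) {
  stopifnot(inherits(traj, "trajectory3d"))
  fps <- traj_fps(traj)
  sec <- classify_length_section(traj$x_cm, geometry)
  lev <- classify_depth_level(traj$z_cm, geometry)
  dt <- 1 / fps
  cs <- table(sec) * dt
  cl <- table(lev) * dt
  list(T_N = unname(cs[["near"]]), T_mid_len = unname(cs[["middle"]]),
       T_F = unname(cs[["far"]]), T_outside = unname(cs[["outside_central"]]),
       T_T = unname(cl[["top"]]), T_mid_depth = unname(cl[["middle"]]),
       T_B = unname(cl[["bottom"]]), analysed_s = nrow(traj) * dt)
}

#' Preference index
#'
#' `T_a / (T_a + T_b)`: the fraction of decided time spent on the `a` side.
#' 0.5 is the chance level. Returns `NA` (with a message) when both times
#' are zero; such trials are excluded from group statistics.
#'
#' @param T_a,T_b Non-negative times (s).
#' @return Value in `[0, 1]`, or `NA` if undefined.
#' @export
preference_index <- function(T_a, T_b) {
  if (any(c(T_a, T_b) < 0)) stop("times must be non-negative")
  tot <- T_a + T_b
  out <- ifelse(tot > 0, T_a / tot, NA_real_)
  if (anyNA(out)) message("preference_index undefined (both times zero)")
  out
}

#' Shoaling time: time spent within a radius of the stimulus
#'
#' Counts frames whose 3D Euclidean fish-stimulus separation is at most
#' `radius_cm` (default 12 cm, four body lengths) and converts to seconds.
#' For the stimulus-free control condition the caller passes the moving
#' replica program of the moving-replica condition as a virtual stimulus.
#'
#' @param fish,stim [trajectory3d()] objects on the same time base.
#' @param radius_cm Shoaling radius (cm), default 12.
#' @return Time (s).
#' @export
shoaling_time <- function(fish, stim, radius_cm = 12) {
  if (nrow(fish) != nrow(stim)) stop("fish and stimulus lengths differ")
  fps <- traj_fps(fish)
  d <- sqrt((fish$x_cm - stim$x_cm)^2 + (fish$y_cm - stim$y_cm)^2 +
              (fish$z_cm - stim$z_cm)^2)
  sum(d <= radius_cm) / fps
}

#' Occupancy and speed histograms
#'
#' Front-view (x, z) and top-view (x, y) position histograms with square
#' bins (default 0.37 cm) and a speed histogram (default bin 0.72 cm/s),
#' each normalized to unit mass.
#'
#' @param traj A [trajectory3d()].
#' @param speeds Optional speed series (cm/s); computed by [kinematics()]
#'   when `NULL`.
#' @param geometry A [tank_geometry()].
#' @param pos_bin_cm Position bin size (cm), default 0.37.
#' @param speed_bin Speed bin size (cm/s), default 0.72.
#' @return List with matrices `front`, `top` (probability mass per bin,
#'   rows = second axis, cols = x) and `speed` (data.frame of bin mids and
#'   mass).
#' @export
density_maps <- function(traj, speeds = NULL, geometry = tank_geometry(),
                         pos_bin_cm = 0.37, speed_bin = 0.72) {
  stopifnot(nrow(traj) > 0)
  if (pos_bin_cm <= 0 || speed_bin <= 0) stop("bin sizes must be positive")
  if (is.null(speeds)) speeds <- kinematics(traj)$speed
  hist2 <- function(u, v, umax, vmax) {
    ub <- seq(0, umax + pos_bin_cm, by = pos_bin_cm)
    vb <- seq(0, vmax + pos_bin_cm, by = pos_bin_cm)
    iu <- findInterval(u, ub, rightmost.closed = TRUE)
    iv <- findInterval(v, vb, rightmost.closed = TRUE)
    m <- matrix(0, length(vb) - 1, length(ub) - 1)
    for (k in seq_along(iu)) m[iv[k], iu[k]] <- m[iv[k], iu[k]] + 1
    m / length(u)
  }
  front <- hist2(traj$x_cm, traj$z_cm, geometry$length_cm,
                 geometry$water_depth_cm)
  top <- hist2(traj$x_cm, traj$y_cm, geometry$length_cm, geometry$width_cm)
  sb <- seq(0, max(speeds) + speed_bin, by = speed_bin)
  cnt <- tabulate(findInterval(speeds, sb, rightmost.closed = TRUE),
                  nbins = length(sb) - 1)
  list(front = front, top = top,
       speed = data.frame(mid = sb[-length(sb)] + speed_bin / 2,
                          mass = cnt / sum(cnt)))
}

#' Per-trial behavioral summary
#'
#' Bundles the per-trial observables: time budgets along the tank length
#' and the water column, the two preference indices, shoaling time against
#' the (possibly virtual) stimulus, and mean speed and acceleration.
#'
#' @param fish Focal-fish [trajectory3d()] (already restricted to the
#'   observation window).
#' @param stim Stimulus [trajectory3d()] on the same time base, or `NULL`.
#' @param geometry A [tank_geometry()].
#' @param radius_cm Shoaling radius (cm), default 12.
#' @param smooth_window Kinematic smoothing window (frames), default 18.
#' @return One-row data.frame.
#' @export
summarize_trial <- function(fish, stim = NULL, geometry,
                            radius_cm = 12, smooth_window = 18) {
  tb <- time_budgets(fish, geometry)
  kin <- kinematics(fish, smooth_window)
  shoal <- if (!is.null(stim)) shoaling_time(fish, stim, radius_cm) else NA_real_
  frac_invalid <- if (!is.null(fish$valid)) mean(!fish$valid) else 0
  if (frac_invalid > 0.10)
    warning(sprintf("trial has %.1f%% invalid frames", 100 * frac_invalid))
  data.frame(
    T_N = tb$T_N, T_mid_len = tb$T_mid_len, T_F = tb$T_F,
    T_outside = tb$T_outside,
    T_T = tb$T_T, T_mid_depth = tb$T_mid_depth, T_B = tb$T_B,
    PI_stimulus = suppressMessages(preference_index(tb$T_N, tb$T_F)),
    PI_bottom = suppressMessages(preference_index(tb$T_B, tb$T_T)),
    shoaling_s = shoal,
    mean_speed = mean(kin$speed),
    mean_accel = mean(kin$acceleration),
    analysed_s = tb$analysed_s,
    frac_invalid = frac_invalid)
}
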