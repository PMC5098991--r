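#' Tank geometry for the three-compartment binary-choice arena
#'
#' Describes the cuboid experimental tank: a central compartment for the
#' focal fish flanked by two lateral stimulus compartments separated by
#' transparent partitions. All coordinates are in cm with the origin at the
#' left-front corner of the tank at the water surface; `x` runs along the
#' tank length, `y` along its width, and `z` increases downward (depth below
#' the water surface).
#'
#' Derived quantities: the central compartment has length
#' `length_cm - 2 * side_compartment_length_cm` (default 54 cm), virtually
#' divided into three equal sections (default 18 cm) along the length for
#' spatial-preference scoring, and the water column is divided into three
#' equal levels (default 5 cm).
#'
#' @param length_cm Tank length (cm), default 74.
#' @param width_cm Tank width (cm), default 30.
#' @param wall_height_cm Tank wall height (cm), default 30.
#' @param water_depth_cm Water depth (cm), default 15.
#' @param side_compartment_length_cm Length of each lateral compartment
#'   (cm), default 10.
#' @param stimulus_side Which lateral compartment holds the stimulus,
#'   `"left"` or `"right"`.
#' @return An object of class `tank_geometry`: a list with the input fields
#'   plus `central_length_cm`, `section_length_cm` and `level_height_cm`.
#' @examples
#' g <- tank_geometry()
#' g$section_length_cm  # 18
#' g$level_height_cm    # 5
#' @export
tank_geometry <- function(length_cm = 74, width_cm = 30, wall_height_cm = 30,
                          water_depth_cm = 15, side_compartment_length_cm = 10,
                          stimulus_side = c("left", "right")) {
  stimulus_side <- match.arg(stimulus_side)
  dims <- c(length_cm, width_cm, wall_height_cm, water_depth_cm,
            side_compartment_length_cm)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all tank dimensions must be strictly positive and finite")
  central <- length_cm - 2 * side_compartment_length_cm
  if (central <= 0)
    stop("central compartment length must be positive")
  if (water_depth_cm > wall_height_cm)
    stop("water depth cannot exceed wall height")
  structure(list(
    length_cm = length_cm,
    width_cm = width_cm,
    wall_height_cm = wall_height_cm,
    water_depth_cm = water_depth_cm,
    side_compartment_length_cm = side_compartment_length_cm,
    stimulus_side = stimulus_side,
    central_length_cm = central,
    section_length_cm = central / 3,
    level_height_cm = water_depth_cm / 3
  ), class = "tank_geometry")
}

#' @export
print.tank_geometry <- function(x, ...) {
  cat(sprintf(
    "Tank %g x %g x %g cm, water depth %g cm; lateral compartments %g cm;\n",
    x$length_cm, x$width_cm, x$wall_height_cm, x$water_depth_cm,
    x$side_compartment_length_cm))
  cat(sprintf("central compartment %g cm -> sections of %g cm; levels of %g cm; stimulus on the %s\n",
              x$central_length_cm, x$section_length_cm, x$level_height_cm,
              x$stimulus_side))
  invisible(x)
}

# Clamp coordinates that overshoot the tank bounds by at most `slack` cm
# (centroid noise near walls); larger overshoots are a tracking failure.
clamp_coord <- function(v, lo, hi, slack = 0.5, what = "coordinate") {
  bad <- v < lo - slack | v > hi + slack
  if (any(bad, na.rm = TRUE))
    stop(sprintf("invalid %s: value outside [%g, %g] by more than %g cm",
                 what, lo, hi, slack))
  pmin(pmax(v, lo), hi)
}

#' Classify positions into the length sections of the central compartment
#'
#' The central compartment is divided along the tank length into three equal
#' sections; classification is relative to the stimulus side, so `"near"` is
#' always the section adjacent to the stimulus compartment. Positions inside
#' a lateral compartment return `"outside_central"`. Boundaries are
#' half-open with the ties going to the section whose lower edge (measured
#' from the stimulus side) they touch; the far end of the central
#' compartment is closed.
#'
#' @param x Numeric vector of positions along the tank length (cm).
#' @param geometry A [tank_geometry()].
#' @return Factor with levels `near`, `middle`, `far`, `outside_central`.
#' @examples
#' g <- tank_geometry(stimulus_side = "left")
#' classify_length_section(c(11, 37, 28), g)  # near, middle, middle
#' @export
classify_length_section <- function(x, geometry) {
  stopifnot(inherits(geometry, "tank_geometry"))
  x <- clamp_coord(x, 0, geometry$length_cm, what = "x")
  # distance from the stimulus-side outer wall
  d <- if (geometry$stimulus_side == "left") x else geometry$length_cm - x
  side <- geometry$side_compartment_length_cm
  sec <- geometry$section_length_cm
  # distance into the central compartment from the stimulus-side partition
  u <- d - side
  lab <- rep("outside_central", length(x))
  inside <- u >= 0 & u <= 3 * sec
  idx <- pmin(floor(u[inside] / sec), 2)  # last section closed at the far wall
  lab[inside] <- c("near", "middle", "far")[idx + 1L]
  factor(lab, levels = c("near", "middle", "far", "outside_central"))
}

#' Classify depths into the three water-column levels
#'
#' The water column is divided into three equal levels; with the default
#' 15 cm depth the levels are top `[0, 5)`, middle `[5, 10)` and bottom
#' `[10, 15]` cm below the water surface (last level closed).
#'
#' @param z Numeric vector of depths below the water surface (cm).
#' @param geometry A [tank_geometry()].
#' @return Factor with levels `top`, `middle`, `bottom`.
#' @examples
#' classify_depth_level(c(14, 7.5, 5), tank_geometry())  # bottom, middle, middle
#' @export
classify_depth_level <- function(z, geometry) {
  stopifnot(inherits(geometry, "tank_geometry"))
  z <- clamp_coord(z, 0, geometry$water_depth_cm, what = "z")
  idx <- pmin(floor(z / geometry$level_height_cm), 2)
  factor(c("top", "middle", "bottom")[idx + 1L],
         levels = c("top", "middle", "bottom"))
}

# x-range of a compartment, used by the simulator for confinement.
compartment_bounds <- function(geometry, compartment = c("central", "left", "right")) {
  compartment <- match.arg(compartment)
  s <- geometry$side_compartment_length_cm
  switch(compartment,
    left = c(0, s),
    central = c(s, geometry$length_cm - s),
    right = c(geometry$length_cm - s, geometry$length_cm))
}

# Compartment holding the stimulus / the empty side, per stimulus_side.
stimulus_compartment <- function(geometry) {
  if (geometry$stimulus_side == "left") "left" else "right"
}
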