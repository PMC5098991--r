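g <- tank_geometry()

test_that("cruise-only fixed-speed simulation reproduces the commanded speed", {
  for (v in c(0.5, 1.69, 5)) {
    tr <- simulate_fish(cruise_params(v), 300, g, seed = 11)
    raw <- sqrt(diff(tr$x_cm)^2 + diff(tr$y_cm)^2 + diff(tr$z_cm)^2) * 30
    expect_equal(mean(raw), v, tolerance = 1e-10)  # reflection preserves speed
    smoothed <- mean(kinematics(tr)$speed)
    expect_lt(abs(smoothed - v) / v, 0.03)
  }
  tr <- simulate_fish(cruise_params(1.69), 600, g, seed = 2)
  expect_lt(abs(mean(kinematics(tr)$speed) - 1.69), 0.05)
})

test_that("degenerate and determinism contracts hold", {
  frozen <- cruise_params(0)
  tr <- simulate_fish(frozen, 10, g, seed = 1)
  expect_equal(diff(range(tr$x_cm)), 0)
  expect_equal(diff(range(tr$z_cm)), 0)
  a <- simulate_fish(locomotion_params(), 60, g, seed = 7)
  b <- simulate_fish(locomotion_params(), 60, g, seed = 7)
  expect_identical(a, b)
  c2 <- simulate_fish(locomotion_params(), 60, g, seed = 8)
  expect_false(identical(a$x_cm, c2$x_cm))
})

test_that("simulated positions stay confined to their compartment", {
  for (comp in c("central", "left")) {
    tr <- simulate_fish(locomotion_params(), 120, g, compartment = comp,
                        seed = 5)
    xb <- roboshoal:::compartment_bounds(g, comp)
    expect_true(all(tr$x_cm >= xb[1] & tr$x_cm <= xb[2]))
    expect_true(all(tr$y_cm >= 0 & tr$y_cm <= g$width_cm))
    expect_true(all(tr$z_cm >= 0 & tr$z_cm <= g$water_depth_cm))
  }
  tight <- tank_geometry(side_compartment_length_cm = 1.5)
  expect_error(simulate_fish(locomotion_params(), 10, tight,
                             compartment = "left"), "wall-repulsion")
})

test_that("mode dwell-time means converge to 1/rate", {
  p <- locomotion_params()
  ms <- simulate_mode_sequence(p, 1e4, seed = 3)
  bouts <- ms$bouts[-nrow(ms$bouts), ]  # last bout truncated at the horizon
  for (m in c("cruise", "freezing", "erratic", "diving")) {
    d <- bouts$dur_s[bouts$mode == m]
    expect_gt(length(d), 20)
    expect_lt(abs(mean(d) - 1 / p$dwell_rates[[m]]) / (1 / p$dwell_rates[[m]]),
              0.10)
  }
  expect_equal(length(ms$frame_modes), 1e4 * 30)
})

test_that("replica program downsampling and interpolation are exact", {
  src <- simulate_fish(locomotion_params(), 600, g, compartment = "left",
                       seed = 9)
  pr <- make_replica_program(src)
  expect_equal(nrow(pr$waypoints), floor(600 / 2.5) + 1)  # 241
  # program passes through every waypoint at its time
  ti <- round(pr$waypoints$t_s * 30) + 1
  expect_equal(pr$trajectory$x_cm[ti], pr$waypoints$x_cm)
  expect_equal(pr$trajectory$y_cm[ti], pr$waypoints$y_cm)
  expect_equal(pr$trajectory$z_cm[ti], pr$waypoints$z_cm)
  expect_error(make_replica_program(src, interval = 500), "two waypoint")
})

test_that("replica program is idempotent on knot-linear input", {
  # source already piecewise-linear between 2.5 s knots
  knots <- data.frame(t = seq(0, 25, by = 2.5),
                      x = c(2, 5, 8, 3, 6, 9, 4, 7, 2, 5, 8),
                      y = seq(4, 24, length.out = 11),
                      z = rep(c(3, 9), length.out = 11))
  t_all <- seq(0, 25, by = 1 / 30)
  src <- trajectory3d(approx(knots$t, knots$x, t_all)$y,
                      approx(knots$t, knots$y, t_all)$y,
                      approx(knots$t, knots$z, t_all)$y, fps = 30)
  pr <- make_replica_program(src)
  n <- nrow(pr$trajectory)
  expect_equal(pr$trajectory$x_cm, src$x_cm[seq_len(n)], tolerance = 1e-9)
  expect_equal(pr$trajectory$z_cm, src$z_cm[seq_len(n)], tolerance = 1e-9)
})

test_that("heading signal has the programmed mean, amplitude and frequency", {
  t <- seq(0, 10 - 1 / 30, by = 1 / 30)  # 20 full cycles at 30 fps
  h <- heading_signal(t, +1)
  expect_equal(mean(h), 45, tolerance = 1e-12)
  expect_equal(mean(heading_signal(t, -1)), 135, tolerance = 1e-12)
  expect_equal(heading_signal(0, -1), 135)  # zero-phase instant
  # peak-to-peak 10 degrees (dense sampling resolves the extrema)
  td <- seq(0, 1, by = 1e-4)
  expect_equal(max(heading_signal(td, 1)) - min(heading_signal(td, 1)), 10,
               tolerance = 1e-4)
  expect_true(all(abs(heading_signal(td, 1) - 45) <= 5 + 1e-12))
  expect_equal(dominant_frequency(heading_signal(t, 1), 30), 2)
})

test_that("planar projection blocks z and only z", {
  src <- simulate_fish(locomotion_params(), 30, g, compartment = "left",
                       seed = 4)
  pr <- make_replica_program(src)
  p2 <- project_rm2d(pr, 7.5)
  expect_true(all(p2$trajectory$z_cm == 7.5))
  expect_identical(p2$trajectory$x_cm, pr$trajectory$x_cm)
  expect_identical(p2$trajectory$y_cm, pr$trajectory$y_cm)
  expect_identical(p2$trajectory$heading_deg, pr$trajectory$heading_deg)
  expect_identical(project_rm2d(p2, 7.5), p2)  # idempotent
  expect_error(project_rm2d(pr, 20), "water column")
})

test_that("coupled-pair generator is seeded, bounded and lag-respecting", {
  a <- simulate_coupled_pair(0.5, lag = 2, length = 500, seed = 6)
  b <- simulate_coupled_pair(0.5, lag = 2, length = 500, seed = 6)
  expect_identical(a, b)
  expect_true(all(a$fish_y >= 0 & a$fish_y <= 30))
  expect_true(all(a$stim_y >= 0 & a$stim_y <= 30))
  expect_error(simulate_coupled_pair(1.2), "c_strength")
  expect_error(simulate_coupled_pair(0.5, lag = 10, length = 5), "length")
})

test_that("rendered views place blobs at the ground-truth centroids", {
  static <- trajectory3d(rep(30, 5), rep(12, 5), rep(6, 5), fps = 30)
  rv <- render_views(list(static), g, scale_px_cm = 3)
  bg <- matrix(200, nrow(rv$top[[1]]), ncol(rv$top[[1]]))
  for (f in 1:5) {
    det <- detect_targets(rv$top[[f]], bg, threshold = 50)
    expect_equal(nrow(det), 1)
    expect_lt(abs(det$cx_px - rv$truth$top_cx_px[f]), 0.5)
    expect_lt(abs(det$cy_px - rv$truth$top_cy_px[f]), 0.5)
  }
  # empty target list: pure background
  rv0 <- render_views(list(), g, scale_px_cm = 3)
  expect_true(all(rv0$top[[1]] == 200))
  # two well-separated targets -> two components in each view
  t2 <- trajectory3d(rep(50, 3), rep(25, 3), rep(12, 3), fps = 30)
  rv2 <- render_views(list(static[1:3, ], t2), g, scale_px_cm = 3)
  expect_equal(nrow(detect_targets(rv2$top[[1]], bg, threshold = 50)), 2)
  out <- trajectory3d(80, 10, 5, fps = 30)
  expect_error(render_views(list(out), g), "field of view")
})
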