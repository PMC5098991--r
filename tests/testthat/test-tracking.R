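g <- tank_geometry()

test_that("PNG frame round-trip preserves intensities", {
  tr <- trajectory3d(rep(30, 3), rep(12, 3), rep(6, 3), fps = 30)
  rv <- render_views(list(tr), g, scale_px_cm = 2)
  dir <- withr::local_tempdir()
  write_frames(rv$top, dir)
  back <- read_frames(dir)
  expect_length(back, 3)
  expect_lt(max(abs(back[[1]] - rv$top[[1]])), 0.5)  # 8-bit quantization
  expect_error(read_frames(withr::local_tempdir()), "no .png")
})

test_that("background estimation is a pixel-wise median", {
  f <- matrix(runif(30), 5, 6)
  expect_equal(estimate_background(list(f, f, f)), f)
  a <- matrix(0, 4, 4); b <- matrix(2, 4, 4)
  expect_equal(estimate_background(list(a, b)), matrix(1, 4, 4))
  expect_error(estimate_background(list()), "empty")
  # a blob covering each pixel in < 50% of frames leaves no trace
  traj <- trajectory3d(seq(15, 60, length.out = 40),
                       seq(5, 25, length.out = 40),
                       rep(7, 40), fps = 30)
  rv <- render_views(list(traj), g, scale_px_cm = 3)
  bg <- estimate_background(rv$top, n_sample = 40)
  expect_equal(max(abs(bg - 200)), 0)
})

test_that("blob detection returns weighted centroids sorted by area", {
  bg <- matrix(100, 40, 60)
  f <- bg
  f[10:13, 20:25] <- 10     # 24-px blob
  f[30:31, 50:52] <- 10     # 6-px blob
  det <- detect_targets(f, bg, threshold = 50, min_area = 4)
  expect_equal(det$area, c(24, 6))
  expect_equal(det$cx_px[1], mean(20:25))
  expect_equal(det$cy_px[1], mean(10:13))
  expect_equal(nrow(detect_targets(bg, bg)), 0)
  # min_area filters specks
  f2 <- bg; f2[5, 5] <- 10
  expect_equal(nrow(detect_targets(f2, bg, min_area = 4)), 0)
})

test_that("track linking follows targets and fills short gaps", {
  # single target, no misses: identity
  det <- lapply(1:20, function(f)
    data.frame(cx_px = f * 2, cy_px = 10 + f, area = 20L))
  tr <- link_tracks(det, 1)[[1]]
  expect_equal(tr$x, (1:20) * 2)
  expect_true(all(tr$valid))
  # 5-frame dropout on a linear path: filled exactly on the line
  det[6:10] <- list(data.frame(cx_px = numeric(0), cy_px = numeric(0),
                               area = integer(0)))
  tr2 <- link_tracks(det, 1)[[1]]
  expect_equal(tr2$x, (1:20) * 2)
  expect_equal(tr2$valid[6:10], rep(FALSE, 5))
  # gap longer than max_gap stays missing
  tr3 <- link_tracks(det, 1, max_gap = 3)[[1]]
  expect_true(all(is.na(tr3$x[6:10])))
})

test_that("two crossing targets keep their identities", {
  n <- 60
  # cross in x while separated in y by more than 2x the frame displacement
  x1 <- seq(10, 60, length.out = n); y1 <- rep(20, n)
  x2 <- seq(60, 10, length.out = n); y2 <- rep(40, n)
  det <- lapply(1:n, function(f)
    data.frame(cx_px = c(x1[f], x2[f]), cy_px = c(y1[f], y2[f]),
               area = c(30L, 25L)))
  trs <- link_tracks(det, 2)
  expect_equal(trs[[1]]$x, x1, tolerance = 1e-12)
  expect_equal(trs[[2]]$x, x2, tolerance = 1e-12)
  expect_equal(trs[[1]]$y, y1)
})

test_that("moving-average smoothing has the stated kernel properties", {
  expect_equal(smooth_ma(rep(3, 50)), rep(3, 50))
  ramp <- seq(0, 10, length.out = 60)
  expect_equal(smooth_ma(ramp)[15:45], ramp[15:45])  # linear passes through
  # impulse response: direct convolution oracle (half-weight even kernel)
  x <- rep(0, 60); x[30] <- 1
  kern <- c(0.5, rep(1, 17), 0.5) / 18
  oracle <- sapply(1:60, function(i) {
    idx <- (i - 9):(i + 9)
    ok <- idx >= 1 & idx <= 60
    sum(kern[ok] * x[idx[ok]]) / sum(kern[ok])
  })
  expect_equal(smooth_ma(x), oracle)
  expect_equal(sort(unique(round(smooth_ma(x), 10))),
               round(c(0, 1 / 36, 1 / 18), 10))  # plateau of 1/18
  expect_error(smooth_ma(1:5, 18), "window")
  # linearity and no range extension
  set.seed(1); a <- rnorm(100); b <- rnorm(100)
  expect_equal(smooth_ma(2 * a + b), 2 * smooth_ma(a) + smooth_ma(b))
  s <- smooth_ma(a)
  expect_gte(min(s), min(a)); expect_lte(max(s), max(a))
})

test_that("view synchronization recovers constructed lags", {
  set.seed(3)
  x <- cumsum(rnorm(600))
  expect_equal(synchronize_views(x, x), 0)
  lagged <- c(rep(x[1], 7), x[1:593])  # front delayed by 7 frames
  expect_equal(synchronize_views(x, lagged), 7)
  expect_error(synchronize_views(rep(1, 100), x[1:100]), "zero variance")
  # noisy recovery at SNR 10 (a few seeds; full calibration in acceptance)
  hits <- sapply(1:10, function(s) {
    set.seed(s)
    sig <- cumsum(rnorm(600)); sig <- sig / sd(sig)
    noisy <- c(rep(sig[1], 5), sig[1:595]) + rnorm(600, 0, sqrt(1 / 10))
    synchronize_views(sig, noisy) == 5
  })
  expect_gte(mean(hits), 0.9)
})

test_that("orthogonal-view fusion inverts the projections", {
  tr <- lissajous_traj(300)
  top <- data.frame(x_cm = tr$x_cm, y_cm = tr$y_cm)
  front <- data.frame(x_cm = tr$x_cm, z_cm = tr$z_cm)
  fused <- fuse_3d(top, front, lag = 0)
  expect_equal(fused$x_cm, tr$x_cm)
  expect_equal(fused$z_cm, tr$z_cm)
  expect_equal(attr(fused, "qc")$x_discrepancy_rms, 0)
  # shifted front view recovered exactly when the lag is supplied
  front4 <- front[c(rep(1, 4), 1:296), ]
  fused4 <- fuse_3d(top, front4, lag = 4)
  expect_equal(fused4$z_cm[5:296], tr$z_cm[5:296])
  expect_error(fuse_3d(top[1:10, ], front[1:10, ], lag = 9), "overlap")
})

test_that("fusion under view noise meets the Monte-Carlo error bound", {
  tr <- lissajous_traj(400)
  rmse <- qc <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    top <- data.frame(x_cm = tr$x_cm + rnorm(400, 0, 0.2),
                      y_cm = tr$y_cm + rnorm(400, 0, 0.2))
    front <- data.frame(x_cm = tr$x_cm + rnorm(400, 0, 0.2),
                        z_cm = tr$z_cm + rnorm(400, 0, 0.2))
    fused <- fuse_3d(top, front, lag = 0)
    rmse[s] <- sqrt(mean((fused$z_cm - tr$z_cm)^2))
    qc[s] <- attr(fused, "qc")$x_discrepancy_rms
  }
  expect_lte(mean(rmse), 0.2 * 1.05)
  expect_lt(abs(mean(qc) - 0.2 * sqrt(2)), 0.03)
})

test_that("rendered views are tracked back to the truth end to end", {
  tr <- lissajous_traj(240)
  rv <- render_views(list(tr), g, scale_px_cm = 3)
  top <- track_view(rv$top, 3)[[1]]
  front <- track_view(rv$front, 3)[[1]]
  lag <- synchronize_views(top$u_cm, front$u_cm, max_lag = 10)
  expect_equal(lag, 0)
  fused <- fuse_3d(
    data.frame(x_cm = top$u_cm, y_cm = top$v_cm, valid = top$valid),
    data.frame(x_cm = front$u_cm, z_cm = front$v_cm, valid = front$valid),
    lag = lag)
  m <- min(nrow(fused), nrow(tr))
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(fused$x_cm[1:m], tr$x_cm[1:m]), 0.5)
  expect_lt(rmse(fused$y_cm[1:m], tr$y_cm[1:m]), 0.5)
  expect_lt(rmse(fused$z_cm[1:m], tr$z_cm[1:m]), 0.5)
})
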