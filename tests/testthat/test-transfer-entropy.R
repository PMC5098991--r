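g <- tank_geometry()

test_that("discretization maps the tank width onto 10 symbols", {
  expect_equal(as.integer(discretize(0)), 0L)
  expect_equal(as.integer(discretize(29.99)), 9L)
  expect_equal(as.integer(discretize(15.0)), 5L)  # floor(15 / 3)
  expect_equal(as.integer(discretize(30)), 9L)    # last bin closed
  expect_error(discretize(5, bins = 1), "bins")
  expect_error(discretize(31), "invalid")
  expect_equal(as.integer(discretize(30.3)), 9L)  # clamped overshoot
})

test_that("plug-in transfer entropy matches the brute-force evaluator", {
  set.seed(100)
  for (i in 1:60) {
    B <- sample(c(2, 5, 10), 1)
    n <- sample(50:500, 1)
    x <- sample(0:(B - 1), n, replace = TRUE)
    # give x some self- and cross-dependence half of the time
    if (i %% 2 == 0) {
      y <- c(x[-1], sample(0:(B - 1), 1))
    } else {
      y <- sample(0:(B - 1), n, replace = TRUE)
    }
    expect_lt(abs(transfer_entropy(x, y, B) - te_oracle(x, y, B)), 1e-12)
  }
})

test_that("copy-process transfer entropy approaches log2(B)", {
  set.seed(7)
  for (B in c(2, 10)) {
    n <- 10000
    y <- sample(0:(B - 1), n, replace = TRUE)
    x <- c(sample(0:(B - 1), 1), y[-n])  # x_{t+1} = y_t
    te <- transfer_entropy(x, y, B)
    expect_lt(abs(te - log2(B)) / log2(B), 0.01)
  }
})

test_that("transfer entropy is non-negative and zero under factorization", {
  set.seed(8)
  for (i in 1:25) {
    B <- sample(2:10, 1)
    n <- sample(20:200, 1)
    x <- sample(0:(B - 1), n, replace = TRUE)
    y <- sample(0:(B - 1), n, replace = TRUE)
    expect_gte(transfer_entropy(x, y, B), -1e-12)
  }
  # constant source: p(x1 | x0, y0) = p(x1 | x0) on every occupied cell
  x <- sample(0:4, 300, replace = TRUE)
  expect_equal(transfer_entropy(x, rep(2L, 300), 5), 0)
  # deterministic self-transition: conditioning on y adds nothing
  x2 <- rep(0:4, 60)
  y2 <- sample(0:4, 300, replace = TRUE)
  expect_equal(transfer_entropy(x2, y2, 5), 0)
  expect_error(transfer_entropy(1:5, 1:4), "lengths differ")
})

test_that("length normalization divides by the sample count", {
  expect_equal(normalize_te(0, 100), 0)
  expect_equal(normalize_te(3.32, 332), 0.01)
  expect_error(normalize_te(1, 0), "positive")
  raw <- c(0.2, 0.5, 0.9)
  expect_true(all(diff(normalize_te(raw, 175)) > 0))  # order-preserving
})

test_that("near-section segment extraction respects the minimum length", {
  fps <- 30
  mk <- function(x) trajectory3d(x, rep(15, length(x)), rep(7, length(x)),
                                 fps = fps)
  stim <- function(n) trajectory3d(rep(5, n), runif(n, 0, 30), rep(7, n),
                                   fps = fps)
  gl <- tank_geometry(stimulus_side = "left")
  # always near
  n <- 18000
  segs <- extract_segments(mk(rep(12, n)), stim(n), gl)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$length, n)
  # alternating 100 near / 100 far: all runs below 175
  x <- rep(c(rep(12, 100), rep(60, 100)), 10)
  expect_length(extract_segments(mk(x), stim(length(x)), gl), 0)
  # scripted run lengths {50, 200, 175, 174} -> keep {200, 175}
  x2 <- c(rep(12, 50), rep(60, 20), rep(15, 200), rep(60, 20),
          rep(20, 175), rep(60, 20), rep(12, 174))
  segs2 <- extract_segments(mk(x2), stim(length(x2)), gl)
  expect_equal(vapply(segs2, `[[`, 0, "length"), c(200, 175))
  # stimulus series cut to the identical windows
  expect_equal(segs2[[1]]$start_frame, 71)
  expect_length(segs2[[1]]$stim_y, 200)
})

test_that("shuffle null brackets independent series and flags coupling", {
  set.seed(31)
  B <- 10
  pair0 <- simulate_coupled_pair(0, length = 800, seed = 41)
  x0 <- discretize(pair0$fish_y); y0 <- discretize(pair0$stim_y)
  n0 <- shuffle_null(x0, y0, n_surrogates = 100, seed = 5)
  expect_true(n0$observed >= n0$lo && n0$observed <= n0$hi)
  pair1 <- simulate_coupled_pair(0.8, length = 3000, seed = 42)
  x1 <- discretize(pair1$fish_y); y1 <- discretize(pair1$stim_y)
  n1 <- shuffle_null(x1, y1, n_surrogates = 100, seed = 5)
  expect_gt(n1$observed, n1$hi)
  n1b <- shuffle_null(x1, y1, n_surrogates = 100, seed = 5)
  expect_identical(n1$values, n1b$values)  # seeded reproducibility
  expect_error(shuffle_null(x1, y1, n_surrogates = 5), "20")
})

test_that("wavelet denoising shrinks noise and preserves structure", {
  expect_equal(wavelet_denoise(rep(4.2, 64)), rep(4.2, 64), tolerance = 1e-12)
  expect_error(wavelet_denoise(rnorm(8)), "too short")
  set.seed(9)
  clean <- 10 + 5 * sin(seq(0, 6 * pi, length.out = 300))
  wins <- replicate(50, {
    noisy <- clean + rnorm(300, 0, 0.3)
    mean((wavelet_denoise(noisy) - clean)^2) < mean((noisy - clean)^2)
  })
  expect_gte(mean(wins), 0.95)
  pure <- replicate(20, {
    e <- rnorm(256)
    var(wavelet_denoise(e)) < var(e)
  })
  expect_true(all(pure))
})

test_that("per-trial segment table reports both directions, normalized", {
  gl <- tank_geometry(stimulus_side = "left")
  n <- 1200
  fish <- trajectory3d(rep(14, n), 15 + 10 * sin(seq_len(n) / 20),
                       rep(7, n), fps = 30)
  stim <- trajectory3d(rep(5, n), 15 + 10 * sin(seq_len(n) / 15),
                       rep(7, n), fps = 30)
  te <- te_segments(fish, stim, gl)
  expect_equal(nrow(te), 1)
  expect_equal(te$length, n)
  expect_equal(te$te_fish_to_stim_norm, te$te_fish_to_stim / n)
  expect_gte(te$te_stim_to_fish, 0)
  # no qualifying segment: zero-row table with the same columns
  far <- trajectory3d(rep(60, n), rep(15, n), rep(7, n), fps = 30)
  expect_equal(nrow(te_segments(far, stim, gl)), 0)
})

test_that("direction analysis produces the long table and summary", {
  seg <- data.frame(condition = c("RM", "RM", "Control"), segment = 1:3,
                    length = c(200, 300, 250),
                    te_fish_to_stim = c(0.2, 0.3, 0.1),
                    te_stim_to_fish = c(0.5, 0.6, 0.1),
                    te_fish_to_stim_norm = c(0.2, 0.3, 0.1) / c(200, 300, 250),
                    te_stim_to_fish_norm = c(0.5, 0.6, 0.1) / c(200, 300, 250))
  da <- direction_analysis(seg)
  expect_equal(nrow(da$long), 6)  # 2 rows per segment
  expect_equal(nrow(da$summary), 4)  # 2 conditions x 2 directions
  rm_rows <- da$summary[da$summary$condition == "RM", ]
  expect_gt(rm_rows$mean[rm_rows$direction == "stim_to_fish"],
            rm_rows$mean[rm_rows$direction == "fish_to_stim"])
})

test_that("directional coupling is recovered on simulated pairs", {
  diffs <- sapply(1:20, function(s) {
    p <- simulate_coupled_pair(0.8, lag = 1, length = 3000, seed = 1000 + s)
    fx <- discretize(p$fish_y); sx <- discretize(p$stim_y)
    transfer_entropy(fx, sx, 10) - transfer_entropy(sx, fx, 10)
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
  # TE(stim -> fish) grows with coupling strength on average
  mte <- sapply(c(0, 0.2, 0.5, 0.8), function(cc) {
    mean(sapply(1:8, function(s) {
      p <- simulate_coupled_pair(cc, lag = 1, length = 2000, seed = 500 + s)
      transfer_entropy(discretize(p$fish_y), discretize(p$stim_y), 10)
    }))
  })
  expect_true(all(diff(mte) > 0))
})
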