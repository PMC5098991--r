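# Independent brute-force transfer-entropy oracle: contingency tables via
# base table(), explicit conditional probabilities, explicit sum over all
# (x_{t+1}, x_t, y_t) realizations.
te_oracle <- function(x, y, B) {
  n <- length(x)
  lv <- 0:(B - 1)
  x1 <- factor(x[-1], levels = lv)
  x0 <- factor(x[-n], levels = lv)
  y0 <- factor(y[-n], levels = lv)
  c3 <- table(x1, x0, y0)
  c_x0y0 <- table(x0, y0)
  c_x1x0 <- table(x1, x0)
  c_x0 <- table(x0)
  N <- n - 1
  te <- 0
  for (a in 1:B) for (b in 1:B) for (cc in 1:B) {
    n3 <- c3[a, b, cc]
    if (n3 == 0) next
    p_joint <- n3 / N
    p_cond_xy <- n3 / c_x0y0[b, cc]
    p_cond_x <- c_x1x0[a, b] / c_x0[b]
    te <- te + p_joint * log2(p_cond_xy / p_cond_x)
  }
  unname(te)
}

# Smooth in-tank 3D test path (Lissajous figure inside the central
# compartment), for tracking fixtures.
lissajous_traj <- function(n_frames, fps = 30, geometry = tank_geometry()) {
  t <- (seq_len(n_frames) - 1) / fps
  xb <- roboshoal:::compartment_bounds(geometry, "central")
  x <- mean(xb) + (diff(xb) / 2 - 6) * sin(2 * pi * 0.05 * t)
  y <- geometry$width_cm / 2 + (geometry$width_cm / 2 - 6) * sin(2 * pi * 0.08 * t + 1)
  z <- geometry$water_depth_cm / 2 + (geometry$water_depth_cm / 2 - 4) *
    sin(2 * pi * 0.06 * t + 2)
  trajectory3d(x, y, z, fps = fps)
}

# Frequency (Hz) of the periodogram maximum of a series sampled at fps.
dominant_frequency <- function(v, fps) {
  v <- v - mean(v)
  n <- length(v)
  sp <- Mod(stats::fft(v))^2
  freqs <- (seq_len(n) - 1) * fps / n
  half <- 2:floor(n / 2)
  freqs[half][which.max(sp[half])]
}
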