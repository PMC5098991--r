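#' Discretize a width-coordinate series into symbols
#'
#' Uniform-width bins over the stated range (default the full 30 cm tank
#' width in 10 bins, one bin per body length). Interior boundaries are
#' half-open with the last bin closed, so every in-range value maps to
#' exactly one of the `B` symbols `0 .. B-1`. Values overshooting the range
#' by at most 0.5 cm (tracking noise) are clamped; larger violations are an
#' error.
#'
#' @param series Numeric vector (cm).
#' @param bins Number of bins `B >= 2`, default 10.
#' @param range Discretization range, default `c(0, 30)`.
#' @return Integer vector of symbols in `0 .. B-1` with attribute `bins`.
#' @export
discretize <- function(series, bins = 10, range = c(0, 30)) {
  if (bins < 2) stop("need at least 2 bins")
  v <- clamp_coord(series, range[1], range[2], what = "series value")
  w <- (range[2] - range[1]) / bins
  sym <- pmin(floor((v - range[1]) / w), bins - 1)
  storage.mode(sym) <- "integer"
  attr(sym, "bins") <- as.integer(bins)
  sym
}

#' Plug-in transfer entropy between two symbol series
#'
#' Histogram (maximum-likelihood) estimate of the transfer entropy from the
#' source process `y` to the target process `x`, both modelled as Markov
#' chains of order one:
#' \deqn{T_{Y \to X} = \sum p(x_{t+1}, x_t, y_t)
#'   \log_2 \frac{p(x_{t+1} \mid x_t, y_t)}{p(x_{t+1} \mid x_t)}}
#' Probabilities are joint frequencies of the observed
#' `(x_{t+1}, x_t, y_t)` triples; unobserved triples contribute zero. The
#' result is non-negative up to floating-point rounding. No pseudocounts
#' or bias correction are applied; use [shuffle_null()] to calibrate the
#' finite-sample bias.
#'
#' @param x Target symbol series (integers in `0 .. B-1`).
#' @param y Source symbol series, same length and alphabet.
#' @param bins Alphabet size `B`; taken from the `bins` attribute when
#'   absent.
#' @return Transfer entropy in bits.
#' @export
transfer_entropy <- function(x, y, bins = NULL) {
  if (length(x) != length(y)) stop("series lengths differ")
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  if (is.null(bins))
    bins <- max(attr(x, "bins") %||% 0, attr(y, "bins") %||% 0,
                max(x, y) + 1)
  B <- as.integer(bins)
  x1 <- x[-1]; x0 <- x[-n]; y0 <- y[-n]
  stopifnot(all(x >= 0 & x < B), all(y >= 0 & y < B))
  N <- n - 1
  # joint and marginal counts via flat indexing
  idx3 <- x1 * B * B + x0 * B + y0 + 1
  c3 <- tabulate(idx3, nbins = B^3)
  c_x0y0 <- tabulate(x0 * B + y0 + 1, nbins = B^2)
  c_x1x0 <- tabulate(x1 * B + x0 + 1, nbins = B^2)
  c_x0 <- tabulate(x0 + 1, nbins = B)
  occ <- which(c3 > 0)
  k <- occ - 1
  kx1 <- k %/% (B * B)
  kx0 <- (k %/% B) %% B
  ky0 <- k %% B
  num <- c3[occ] * c_x0[kx0 + 1]
  den <- c_x0y0[kx0 * B + ky0 + 1] * c_x1x0[kx1 * B + kx0 + 1]
  sum(c3[occ] / N * log2(num / den))
}

#' Length-normalize a raw transfer-entropy estimate
#'
#' Divides the raw per-segment estimate (bits) by the segment sample
#' count, giving bits per sample, so segments of different durations are
#' comparable.
#'
#' @param raw Raw transfer entropy (bits).
#' @param length Segment length in samples (> 0).
#' @return Bits per sample.
#' @export
normalize_te <- function(raw, length) {
  if (any(length <= 0)) stop("segment length must be positive")
  raw / length
}

#' Extract near-section fish-stimulus segment pairs
#'
#' Keeps the maximal runs of consecutive frames during which the fish is in
#' the length section nearest the stimulus, discards runs shorter than
#' `min_len` samples (default 175), and cuts the stimulus series to the
#' identical frame windows. The width coordinate (y) of both animals is
#' returned, the signal pair entering the transfer-entropy estimate.
#'
#' @param fish,stim [trajectory3d()] objects on the same time base.
#' @param geometry A [tank_geometry()].
#' @param min_len Minimum segment length (samples), default 175.
#' @return List of segments: each a list with `fish_y`, `stim_y`,
#'   `start_frame`, `length`. May be empty.
#' @export
extract_segments <- function(fish, stim, geometry, min_len = 175) {
  if (nrow(fish) != nrow(stim)) stop("fish and stimulus lengths differ")
  near <- classify_length_section(fish$x_cm, geometry) == "near"
  r <- rle(near)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_len)
  lapply(keep, function(i) {
    idx <- starts[i]:ends[i]
    list(fish_y = fish$y_cm[idx], stim_y = stim$y_cm[idx],
         start_frame = starts[i], length = length(idx))
  })
}

#' Shuffle-surrogate null distribution for a transfer-entropy estimate
#'
#' Recomputes the transfer entropy from the source to the target on
#' time-shuffled source surrogates, destroying the coupling while keeping
#' the source's symbol distribution. The resulting null quantifies the
#' finite-sample (positive) bias of the plug-in estimator.
#'
#' Two shuffling schemes are available. The default, `"rotate"`, applies a
#' random circular time shift (at least `margin` samples), which preserves
#' the source's serial autocorrelation — the correct null for positional
#' series, which are strongly autocorrelated; a full random permutation
#' (`"permute"`) whitens the source and mis-calibrates the band for such
#' series (in either direction, depending on the series length).
#'
#' @param x Target symbol series.
#' @param y Source symbol series.
#' @param n_surrogates Number of surrogates (>= 20), default 200.
#' @param bins Alphabet size (see [transfer_entropy()]).
#' @param seed Optional integer seed.
#' @param method `"rotate"` (circular time shift, default) or `"permute"`.
#' @param margin Minimum circular shift (samples) for `"rotate"`.
#' @return List with `observed`, `mean`, `lo` and `hi` (2.5% / 97.5%
#'   percentiles) and the surrogate `values`.
#' @export
shuffle_null <- function(x, y, n_surrogates = 200, bins = NULL, seed = NULL,
                         method = c("rotate", "permute"), margin = 20) {
  if (n_surrogates < 20) stop("need at least 20 surrogates")
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  if (method == "rotate" && n <= 2 * margin)
    stop("series too short for rotation surrogates with this margin")
  obs <- transfer_entropy(x, y, bins)
  vals <- vapply(seq_len(n_surrogates), function(i) {
    ys <- if (method == "permute") {
      sample(y)
    } else {
      k <- sample(margin:(n - margin), 1)
      c(y[(k + 1):n], y[seq_len(k)])
    }
    transfer_entropy(x, ys, bins)
  }, 0)
  q <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  list(observed = obs, mean = mean(vals), lo = q[1], hi = q[2],
       values = vals)
}

#' Per-segment bidirectional transfer entropy for one trial
#'
#' Full per-trial chain: optional wavelet denoising of the width
#' coordinates, near-section segment extraction, discretization over the
#' tank width, plug-in transfer entropy in both directions, and per-segment
#' length normalization.
#'
#' @param fish,stim [trajectory3d()] objects on the same time base.
#' @param geometry A [tank_geometry()].
#' @param bins Number of symbols, default 10.
#' @param min_len Minimum segment length, default 175.
#' @param denoise Apply [wavelet_denoise()] to the width coordinates of
#'   each segment before discretization (default TRUE; disabled
#'   automatically for segments shorter than the decomposition minimum).
#' @return data.frame with one row per segment: `segment`, `length`,
#'   `te_fish_to_stim`, `te_stim_to_fish` (bits) and their
#'   length-normalized counterparts (bits per sample). Zero rows when no
#'   segment qualifies.
#' @export
te_segments <- function(fish, stim, geometry, bins = 10, min_len = 175,
                        denoise = TRUE) {
  segs <- extract_segments(fish, stim, geometry, min_len)
  if (!length(segs))
    return(data.frame(segment = integer(0), length = integer(0),
                      te_fish_to_stim = numeric(0),
                      te_stim_to_fish = numeric(0),
                      te_fish_to_stim_norm = numeric(0),
                      te_stim_to_fish_norm = numeric(0)))
  rows <- lapply(seq_along(segs), function(i) {
    s <- segs[[i]]
    fy <- s$fish_y; sy <- s$stim_y
    if (denoise && s$length >= 32) {
      fy <- wavelet_denoise(fy)
      sy <- wavelet_denoise(sy)
    }
    rng <- c(0, geometry$width_cm)
    fx <- discretize(pmin(pmax(fy, rng[1]), rng[2]), bins, rng)
    sx <- discretize(pmin(pmax(sy, rng[1]), rng[2]), bins, rng)
    fs <- transfer_entropy(sx, fx, bins)  # fish (source) -> stimulus
    sf <- transfer_entropy(fx, sx, bins)  # stimulus (source) -> fish
    data.frame(segment = i, length = s$length,
               te_fish_to_stim = fs, te_stim_to_fish = sf,
               te_fish_to_stim_norm = normalize_te(fs, s$length),
               te_stim_to_fish_norm = normalize_te(sf, s$length))
  })
  do.call(rbind, rows)
}

#' Direction-of-information long table and condition summary
#'
#' Reshapes per-trial segment results (grouped by experimental condition)
#' into the long format consumed by the direction-by-segment ANOVA, and
#' summarizes per-condition, per-direction means and standard errors of the
#' length-normalized transfer entropy.
#'
#' @param trials data.frame of segment results with a `condition` column
#'   and the columns produced by [te_segments()].
#' @return List with `long` (condition, segment, direction, te_norm) and
#'   `summary` (condition, direction, mean, se, n_segments).
#' @export
direction_analysis <- function(trials) {
  stopifnot(nrow(trials) >= 1, "condition" %in% names(trials))
  long <- rbind(
    data.frame(condition = trials$condition, segment = trials$segment,
               direction = "fish_to_stim",
               te_norm = trials$te_fish_to_stim_norm),
    data.frame(condition = trials$condition, segment = trials$segment,
               direction = "stim_to_fish",
               te_norm = trials$te_stim_to_fish_norm))
  long <- long[order(long$condition, long$segment, long$direction), ]
  rownames(long) <- NULL
  agg <- stats::aggregate(te_norm ~ condition + direction, long, function(v)
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v)))
  summary <- data.frame(condition = agg$condition, direction = agg$direction,
                        mean = agg$te_norm[, "mean"], se = agg$te_norm[, "se"],
                        n_segments = agg$te_norm[, "n"])
  list(long = long, summary = summary)
}
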