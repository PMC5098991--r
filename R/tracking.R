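#' Read a directory of PNG frames as grayscale matrices
#'
#' Frames are read in lexicographic filename order and collapsed to
#' grayscale intensities on the 0-255 scale (channels averaged). Users
#' pre-extract video into per-frame images; container decoding is out of
#' scope.
#'
#' @param path Directory containing `.png` frames.
#' @return List of numeric matrices.
#' @export
read_frames <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("reading PNG frames requires the 'png' package")
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no .png frames found in ", path)
  lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                        c(1, 2), mean)
    a * 255
  })
}

#' Write grayscale frames to a directory of PNGs
#'
#' @param frames List of matrices on the 0-255 scale (clipped).
#' @param path Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(frames, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("writing PNG frames requires the 'png' package")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(frames), function(i) {
    f <- file.path(path, sprintf("frame_%05d.png", i))
    png::writePNG(pmin(pmax(frames[[i]], 0), 255) / 255, f)
    f
  }, "")
  invisible(paths)
}

#' Estimate the static background of a frame sequence
#'
#' Pixel-wise median over a uniformly subsampled set of frames. With a
#' static camera and a target that covers any given pixel in fewer than
#' half of the frames, the median recovers the clean background exactly.
#'
#' @param frames List of grayscale matrices, all the same dimension.
#' @param n_sample Number of frames entering the median (uniformly spaced
#'   over the sequence; capped at the sequence length).
#' @return A background matrix.
#' @export
estimate_background <- function(frames, n_sample = 50) {
  if (length(frames) < 1) stop("empty frame sequence")
  dims <- dim(frames[[1]])
  idx <- unique(round(seq(1, length(frames),
                          length.out = min(n_sample, length(frames)))))
  arr <- vapply(frames[idx], function(f) {
    stopifnot(identical(dim(f), dims))
    f
  }, matrix(0, dims[1], dims[2]))
  apply(arr, c(1, 2), stats::median)
}

# 8-connected component labeling of a logical mask (two-pass scan with
# union-find); masks here are tiny so plain R is adequate.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j]) next
    nb <- integer(0)
    if (i > 1 && labels[i - 1, j]) nb <- c(nb, labels[i - 1, j])
    if (j > 1) {
      if (labels[i, j - 1]) nb <- c(nb, labels[i, j - 1])
      if (i > 1 && labels[i - 1, j - 1]) nb <- c(nb, labels[i - 1, j - 1])
      if (i < nr && labels[i + 1, j - 1]) nb <- c(nb, labels[i + 1, j - 1])
    }
    if (!length(nb)) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      labels[i, j] <- nxt
    } else {
      roots <- vapply(unique(nb), find, 0L)
      r <- min(roots)
      labels[i, j] <- r
      for (o in roots) parent[o] <- r
    }
  }
  if (nxt == 0L) return(labels)
  roots <- vapply(seq_len(nxt), find, 0L)
  relab <- match(roots, unique(roots))
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  labels
}

#' Detect target blobs by background subtraction
#'
#' Thresholds the absolute difference to the background, labels
#' 8-connected components, drops components smaller than `min_area` pixels
#' and returns intensity-weighted centroids (weights = absolute background
#' difference), sorted by area, largest first. Centroid pixel coordinates
#' follow the convention that pixel `j` is centred at `j` (so cm =
#' `(px - 0.5) / scale`).
#'
#' @param frame,background Grayscale matrices of equal dimension.
#' @param threshold Intensity threshold on `|frame - background|`.
#' @param min_area Minimum component area in pixels.
#' @return data.frame with columns `cx_px` (column direction), `cy_px`
#'   (row direction), `area`; zero rows if nothing detected.
#' @export
detect_targets <- function(frame, background, threshold = 50, min_area = 4) {
  stopifnot(identical(dim(frame), dim(background)))
  d <- abs(frame - background)
  mask <- d > threshold
  if (!any(mask))
    return(data.frame(cx_px = numeric(0), cy_px = numeric(0),
                      area = integer(0)))
  labels <- label_components(mask)
  ids <- sort(unique(labels[labels > 0L]))
  out <- lapply(ids, function(id) {
    sel <- which(labels == id, arr.ind = TRUE)
    if (nrow(sel) < min_area) return(NULL)
    w <- d[sel]
    data.frame(cx_px = sum(sel[, 2] * w) / sum(w),
               cy_px = sum(sel[, 1] * w) / sum(w),
               area = nrow(sel))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    return(data.frame(cx_px = numeric(0), cy_px = numeric(0),
                      area = integer(0)))
  out[order(-out$area), , drop = FALSE]
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour assignment frame to frame for a fixed number of
#' targets. Tracks are seeded from the first frame holding at least
#' `n_targets` detections (largest blobs first). Frames where a track has
#' no matched detection are gap-filled by linear interpolation when the gap
#' is at most `max_gap` frames; longer gaps (and leading/trailing misses)
#' stay `NA` and are flagged invalid.
#'
#' @param detections List (one element per frame) of data.frames as
#'   returned by [detect_targets()].
#' @param n_targets Number of targets to track (>= 1).
#' @param max_gap Longest gap (frames) bridged by interpolation.
#' @return List of `n_targets` data.frames with columns `frame`, `x`, `y`,
#'   `valid` (TRUE = detected, FALSE = interpolated or missing), in the
#'   units of the detections.
#' @export
link_tracks <- function(detections, n_targets = 1, max_gap = 15) {
  stopifnot(n_targets >= 1)
  n <- length(detections)
  X <- matrix(NA_real_, n, n_targets)
  Y <- matrix(NA_real_, n, n_targets)
  last <- matrix(NA_real_, n_targets, 2)  # last known position per track
  seeded <- FALSE
  n_ambiguous <- 0L
  for (f in seq_len(n)) {
    det <- detections[[f]]
    if (!seeded) {
      if (!is.null(det) && nrow(det) >= n_targets) {
        for (k in seq_len(n_targets)) {
          X[f, k] <- det$cx_px[k]; Y[f, k] <- det$cy_px[k]
          last[k, ] <- c(det$cx_px[k], det$cy_px[k])
        }
        seeded <- TRUE
      }
      next
    }
    if (is.null(det) || nrow(det) == 0) next
    if (nrow(det) > n_targets) n_ambiguous <- n_ambiguous + 1L
    # greedy: repeatedly take the globally closest (track, detection) pair
    dmat <- outer(last[, 1], det$cx_px, `-`)^2 + outer(last[, 2], det$cy_px, `-`)^2
    dmat <- matrix(dmat, n_targets, nrow(det))
    free_t <- rep(TRUE, n_targets); free_d <- rep(TRUE, nrow(det))
    repeat {
      sub <- dmat
      sub[!free_t, ] <- Inf; sub[, !free_d] <- Inf
      if (all(!is.finite(sub))) break
      ij <- arrayInd(which.min(sub), dim(sub))
      k <- ij[1]; d <- ij[2]
      X[f, k] <- det$cx_px[d]; Y[f, k] <- det$cy_px[d]
      last[k, ] <- c(det$cx_px[d], det$cy_px[d])
      free_t[k] <- FALSE; free_d[d] <- FALSE
      if (!any(free_t) || !any(free_d)) break
    }
  }
  if (n_ambiguous > 0)
    message(sprintf("link_tracks: %d frames had more detections than targets",
                    n_ambiguous))
  lapply(seq_len(n_targets), function(k) {
    x <- X[, k]; y <- Y[, k]
    valid <- !is.na(x)
    data.frame(frame = seq_len(n), x = fill_gaps(x, max_gap),
               y = fill_gaps(y, max_gap), valid = valid)
  })
}

# Linear interpolation across interior NA runs of length <= max_gap.
fill_gaps <- function(v, max_gap) {
  ok <- which(!is.na(v))
  if (length(ok) < 2) return(v)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- v
  for (i in seq_along(r$lengths)) {
    if (!r$values[i] || r$lengths[i] > max_gap) next
    s <- starts[i]; e <- ends[i]
    if (s == 1 || e == length(v)) next  # leading/trailing runs stay NA
    out[s:e] <- v[s - 1] + (v[e + 1] - v[s - 1]) * (seq_len(e - s + 1)) / (e - s + 2)
  }
  out
}

#' Centred moving-average smoothing
#'
#' Suppresses tracking noise with a centred moving average of `window`
#' frames. Odd windows use a flat kernel; even windows use the standard
#' centred form of length `window + 1` with half weights at the two ends
#' (so a linear ramp passes through unchanged). At the series edges the
#' kernel shrinks to the available support and is renormalized, preserving
#' the series length.
#'
#' @param series Numeric vector.
#' @param window Window size in frames (default 18).
#' @return Smoothed vector, same length as the input.
#' @export
smooth_ma <- function(series, window = 18) {
  n <- length(series)
  stopifnot(window >= 1)
  if (window > n) stop("window longer than the series")
  if (window == 1) return(series)
  if (window %% 2 == 1) {
    kern <- rep(1, window); h <- (window - 1) / 2
  } else {
    kern <- c(0.5, rep(1, window - 1), 0.5); h <- window / 2
  }
  kern <- kern / sum(kern)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    w <- kern[(lo - i + h + 1):(hi - i + h + 1)]
    out[i] <- sum(series[lo:hi] * w) / sum(w)
  }
  out
}

#' Synchronize the two camera views by cross-correlation
#'
#' Both views observe the tank-length coordinate x; the lag maximizing the
#' normalized cross-correlation of the two x-series over a bounded search
#' window aligns them. A positive lag means the front view is delayed by
#' that many frames relative to the top view.
#'
#' @param top_x,front_x Numeric x-coordinate series of the two views.
#' @param max_lag Search half-window (frames), default 60.
#' @return Integer lag (frames).
#' @export
synchronize_views <- function(top_x, front_x, max_lag = 60) {
  n <- min(length(top_x), length(front_x))
  top_x <- top_x[seq_len(n)]; front_x <- front_x[seq_len(n)]
  if (stats::sd(top_x, na.rm = TRUE) == 0 ||
      stats::sd(front_x, na.rm = TRUE) == 0)
    stop("cannot synchronize: an x-series has zero variance")
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) {
    if (L >= 0) {
      a <- top_x[seq_len(n - L)]; b <- front_x[(1 + L):n]
    } else {
      a <- top_x[(1 - L):n]; b <- front_x[seq_len(n + L)]
    }
    if (length(a) < 3) return(-Inf)
    suppressWarnings(stats::cor(a, b, use = "complete.obs"))
  }, 0)
  lags[which.max(cc)]
}

#' Fuse two orthogonal 2D views into a 3D trajectory
#'
#' Concatenates the orthogonal views: x and y come from the top view, z
#' from the front view, after shifting the front view by `lag` frames. The
#' front view's own x-series is used only for quality control, reported as
#' the RMS discrepancy against the top-view x over the overlap.
#'
#' @param top data.frame with columns `x_cm`, `y_cm` (and optionally
#'   `valid`) from the top view.
#' @param front data.frame with columns `x_cm`, `z_cm` (and optionally
#'   `valid`) from the front view.
#' @param lag Front-view delay in frames (from [synchronize_views()]).
#' @param fps Frame rate, default 30.
#' @return A [trajectory3d()] (provenance `"fused"`) with a `valid` column,
#'   plus attribute `qc` holding the RMS x-discrepancy and overlap length.
#' @export
fuse_3d <- function(top, front, lag = 0, fps = 30) {
  nt <- nrow(top); nf <- nrow(front)
  # top frame t aligns with front frame t + lag
  t_idx <- seq_len(nt)
  f_idx <- t_idx + lag
  keep <- f_idx >= 1 & f_idx <= nf
  if (sum(keep) < fps) stop("aligned overlap shorter than 1 s")
  t_idx <- t_idx[keep]; f_idx <- f_idx[keep]
  x <- top$x_cm[t_idx]; y <- top$y_cm[t_idx]; z <- front$z_cm[f_idx]
  valid <- rep(TRUE, length(t_idx))
  if (!is.null(top$valid)) valid <- valid & top$valid[t_idx]
  if (!is.null(front$valid)) valid <- valid & front$valid[f_idx]
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  xq <- front$x_cm[f_idx]
  qc_rms <- sqrt(mean((x[ok] - xq[ok])^2))
  tr <- trajectory3d(x[ok], y[ok], z[ok], fps = fps, provenance = "fused",
                     valid = valid[ok])
  attr(tr, "qc") <- list(lag = lag, x_discrepancy_rms = qc_rms,
                         n_overlap = sum(ok), n_dropped = sum(!ok))
  tr
}

#' Track one rendered view end to end
#'
#' Convenience wrapper: background estimation, per-frame blob detection,
#' nearest-neighbour linking, pixel-to-cm conversion and moving-average
#' smoothing for a single view.
#'
#' @param frames List of grayscale matrices.
#' @param scale_px_cm Pixels per cm.
#' @param n_targets Number of targets.
#' @param threshold,min_area Passed to [detect_targets()].
#' @param window Smoothing window (frames), default 18.
#' @param max_gap Longest interpolated gap (frames), default 15.
#' @return List of data.frames (`frame`, `u_cm`, `v_cm`, `valid`), one per
#'   target; `u` is the horizontal (x) axis, `v` the view's second axis.
#' @export
track_view <- function(frames, scale_px_cm, n_targets = 1, threshold = 50,
                       min_area = 4, window = 18, max_gap = 15) {
  bg <- estimate_background(frames)
  dets <- lapply(frames, detect_targets, background = bg,
                 threshold = threshold, min_area = min_area)
  tracks <- link_tracks(dets, n_targets = n_targets, max_gap = max_gap)
  lapply(tracks, function(tr) {
    u <- (tr$x - 0.5) / scale_px_cm
    v <- (tr$y - 0.5) / scale_px_cm
    ok <- !is.na(u)
    u[ok] <- smooth_ma_na(u, window)[ok]
    v[ok] <- smooth_ma_na(v, window)[ok]
    data.frame(frame = tr$frame, u_cm = u, v_cm = v, valid = tr$valid)
  })
}

# moving average tolerant of leading/trailing NAs (smooths the inner part)
smooth_ma_na <- function(v, window) {
  ok <- which(!is.na(v))
  if (!length(ok)) return(v)
  rng <- ok[1]:ok[length(ok)]
  inner <- v[rng]
  if (any(is.na(inner)) || window > length(inner)) return(v)
  v[rng] <- smooth_ma(inner, window)
  v
}
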