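#' Render synthetic two-view image sequences of tank trajectories
#'
#' Produces the orthogonal camera views of the assay as grayscale matrices:
#' the top view images the (x, y) plane and the front view the (x, z)
#' plane. Each target is drawn as a filled dark ellipse (default 3 x 1 cm,
#' the footprint of an adult zebrafish) on a uniform light background,
#' optionally with additive Gaussian pixel noise. Pixel `j` spans
#' `((j-1)/scale, j/scale]` cm, so pixel centres sit at `(j - 0.5)/scale`
#' cm; the ground-truth table reports true centroids in both cm and pixel
#' units under that convention.
#'
#' @param trajs List of [trajectory3d()] objects (one per target), equal
#'   length and frame rate.
#' @param geometry A [tank_geometry()].
#' @param scale_px_cm Pixels per cm (default 3, i.e. 30 px per 10 cm).
#' @param body_cm Ellipse semi-axes will be half these: c(length, width) of
#'   the rendered body (cm).
#' @param background Background intensity (default 200).
#' @param foreground Blob intensity (default 30).
#' @param noise_sd Gaussian pixel noise standard deviation (default 0).
#' @param seed Optional seed for the pixel noise.
#' @return List with `top` and `front` (lists of matrices, one per frame),
#'   `truth` (data.frame: frame, target, x_cm, y_cm, z_cm, and px
#'   centroids per view) and `scale_px_cm`.
#' @export
render_views <- function(trajs, geometry, scale_px_cm = 3,
                         body_cm = c(3, 1), background = 200,
                         foreground = 30, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(geometry, "tank_geometry"), scale_px_cm > 0)
  if (!is.null(seed)) set.seed(seed)
  n_frames <- if (length(trajs)) nrow(trajs[[1]]) else 0L
  for (tr in trajs) {
    stopifnot(inherits(tr, "trajectory3d"), nrow(tr) == n_frames)
    if (any(tr$x_cm < 0 | tr$x_cm > geometry$length_cm |
            tr$y_cm < 0 | tr$y_cm > geometry$width_cm |
            tr$z_cm < 0 | tr$z_cm > geometry$water_depth_cm))
      stop("target leaves the field of view")
  }
  if (length(trajs) == 0 && n_frames == 0) n_frames <- 1L
  nx <- ceiling(geometry$length_cm * scale_px_cm)
  ny_top <- ceiling(geometry$width_cm * scale_px_cm)
  ny_front <- ceiling(geometry$water_depth_cm * scale_px_cm)
  a <- body_cm[1] / 2; b <- body_cm[2] / 2
  centres <- function(n) (seq_len(n) - 0.5) / scale_px_cm
  cx <- centres(nx); cy <- centres(ny_top); cz <- centres(ny_front)

  draw <- function(img, u0, v0, ucent, vcent) {
    # bounding box in pixels, then exact ellipse test on pixel centres
    ui <- which(abs(ucent - u0) <= a + 1 / scale_px_cm)
    vi <- which(abs(vcent - v0) <= b + 1 / scale_px_cm)
    if (!length(ui) || !length(vi)) return(img)
    du <- (ucent[ui] - u0) / a
    dv <- (vcent[vi] - v0) / b
    inside <- outer(dv^2, du^2, `+`) <= 1
    sub <- img[vi, ui, drop = FALSE]
    sub[inside] <- foreground
    img[vi, ui] <- sub
    img
  }

  top <- front <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    it <- matrix(background, ny_top, nx)
    ifr <- matrix(background, ny_front, nx)
    rows <- list()
    for (k in seq_along(trajs)) {
      p <- trajs[[k]][f, ]
      it <- draw(it, p$x_cm, p$y_cm, cx, cy)
      ifr <- draw(ifr, p$x_cm, p$z_cm, cx, cz)
      rows[[k]] <- data.frame(
        frame = f, target = k, x_cm = p$x_cm, y_cm = p$y_cm, z_cm = p$z_cm,
        top_cx_px = p$x_cm * scale_px_cm + 0.5,
        top_cy_px = p$y_cm * scale_px_cm + 0.5,
        front_cx_px = p$x_cm * scale_px_cm + 0.5,
        front_cy_px = p$z_cm * scale_px_cm + 0.5)
    }
    if (noise_sd > 0) {
      it <- it + matrix(stats::rnorm(length(it), 0, noise_sd), nrow(it))
      ifr <- ifr + matrix(stats::rnorm(length(ifr), 0, noise_sd), nrow(ifr))
    }
    top[[f]] <- it; front[[f]] <- ifr
    truth[[f]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  list(top = top, front = front,
       truth = do.call(rbind, truth), scale_px_cm = scale_px_cm)
}
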