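#' Uniformly sampled 3D trajectory
#'
#' Light container used throughout the pipeline: a data.frame with columns
#' `frame`, `t_s`, `x_cm`, `y_cm`, `z_cm` (plus optional extras such as
#' `mode` or `valid`), a frame-rate attribute and a provenance label
#' (`"simulated"`, `"tracked"` or `"fused"`).
#'
#' @param x,y,z Numeric coordinate vectors (cm), equal length.
#' @param fps Frame rate (frames per second).
#' @param provenance Character label recording how the trajectory was made.
#' @param ... Additional equal-length columns (e.g. `mode`, `valid`).
#' @return A data.frame of class `trajectory3d`.
#' @export
trajectory3d <- function(x, y, z, fps = 30, provenance = "simulated", ...) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, fps > 0)
  if (n > 0 && any(!is.finite(c(x, y, z))))
    stop("trajectory coordinates must be finite")
  extra <- list(...)
  df <- data.frame(frame = seq_len(n), t_s = (seq_len(n) - 1) / fps,
                   x_cm = x, y_cm = y, z_cm = z)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  attr(df, "fps") <- fps
  attr(df, "provenance") <- provenance
  class(df) <- c("trajectory3d", "data.frame")
  df
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("3D trajectory: %d frames at %g fps (%.1f s), provenance '%s'\n",
              nrow(x), traj_fps(x), nrow(x) / traj_fps(x),
              attr(x, "provenance") %||% "unknown"))
  print(utils::head(as.data.frame(x), 3))
  invisible(x)
}

#' @export
`[.trajectory3d` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "fps") <- attr(x, "fps")
    attr(out, "provenance") <- attr(x, "provenance")
    class(out) <- class(x)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

traj_fps <- function(traj) {
  fps <- attr(traj, "fps")
  if (is.null(fps)) stop("trajectory has no frame-rate attribute")
  fps
}

# Restrict a trajectory to rows after the habituation cutoff (seconds).
drop_habituation <- function(traj, cutoff_s = 600) {
  keep <- traj$t_s >= cutoff_s
  out <- traj[keep, , drop = FALSE]
  attr(out, "fps") <- attr(traj, "fps")
  attr(out, "provenance") <- attr(traj, "provenance")
  class(out) <- class(traj)
  out
}
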