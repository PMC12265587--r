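#' Acquisition time grid
#'
#' Builds the frame/interpolation time grid on which trajectories are
#' simulated and the exposure integral is discretized. Each of the `n_frames`
#' frames spans one `frame_period` t_F; the camera collects light during the
#' first `exposure` seconds t_E of a frame and is blind during the dead time
#' t_F - t_E. The `k_interp` intraframe positions are placed at the midpoints
#' of `k_interp` equal sub-intervals of the exposure window, so the exposure
#' integral discretized over them is a midpoint rule.
#'
#' @param n_frames Number of frames N (positive integer).
#' @param k_interp Number of intraframe interpolation points K (positive
#'   integer).
#' @param frame_period Frame period t_F in seconds.
#' @param exposure Exposure period t_E in seconds; must satisfy
#'   `0 < exposure <= frame_period`.
#' @return An object of class `spt_time_grid` with fields `n_frames`,
#'   `k_interp`, `frame_period`, `exposure`, and `times` (an N x K matrix of
#'   seconds, strictly increasing in flattened (n, k) order).
#' @examples
#' g <- time_grid(n_frames = 15, k_interp = 16)
#' dim(g$times)
#' @export
time_grid <- function(n_frames, k_interp = 16L,
                      frame_period = 0.033, exposure = 0.030) {
  n_frames <- as.integer(check_scalar(n_frames, "n_frames", lower = 1))
  k_interp <- as.integer(check_scalar(k_interp, "k_interp", lower = 1))
  check_scalar(frame_period, "frame_period", lower = 0, open_lower = TRUE)
  check_scalar(exposure, "exposure", lower = 0, open_lower = TRUE,
               upper = frame_period)
  frame_starts <- (seq_len(n_frames) - 1) * frame_period
  mids <- (seq_len(k_interp) - 0.5) * exposure / k_interp
  times <- outer(frame_starts, mids, `+`)
  structure(
    list(n_frames = n_frames, k_interp = k_interp,
         frame_period = frame_period, exposure = exposure, times = times),
    class = "spt_time_grid")
}

#' @export
print.spt_time_grid <- function(x, ...) {
  cat(sprintf(
    "<spt_time_grid> N = %d frames x K = %d (t_F = %g s, t_E = %g s, dead = %g s)\n",
    x$n_frames, x$k_interp, x$frame_period, x$exposure,
    x$frame_period - x$exposure))
  invisible(x)
}

# Flattened simulation times t_ell, ell = 1..N*K (row-major over frames).
grid_times <- function(grid) {
  as.vector(t(grid$times))
}

# Lag times Delta t_ell between successive flattened grid points.
grid_dts <- function(grid) {
  diff(grid_times(grid))
}

is_time_grid <- function(x) inherits(x, "spt_time_grid")
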