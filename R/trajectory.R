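#' Single-particle trajectory container
#'
#' Positions are stored as an N x K x 3 array of micrometres on a
#' [time_grid()]; axis order is (x, y, z). The flattened (n, k) order is the
#' simulation order ell = 1..N*K.
#'
#' @param positions N x K x 3 numeric array (micrometres), or an (N*K) x 3
#'   matrix in flattened row-major frame order.
#' @param grid A [time_grid()].
#' @param model Motion-model label, one of
#'   `c("BM", "DBM", "ATTM", "CTRW", "FBM", "LW", "SBM")`.
#' @param params Named list of ground-truth generative parameters.
#' @param seed Integer seed the trajectory was generated from (or `NA`).
#' @return An object of class `spt_trajectory`.
#' @export
trajectory <- function(positions, grid, model = "BM", params = list(),
                       seed = NA_integer_) {
  stopifnot(is_time_grid(grid))
  n <- grid$n_frames
  k <- grid$k_interp
  if (is.matrix(positions)) {
    if (nrow(positions) != n * k || ncol(positions) != 3L) {
      stop_invalid("flattened positions must be (N*K) x 3")
    }
    positions <- flat_to_array(positions, grid)
  }
  if (!identical(dim(positions), c(n, k, 3L)) &&
      !identical(dim(positions), as.integer(c(n, k, 3)))) {
    stop_invalid("positions must be an N x K x 3 array matching the grid")
  }
  if (!all(is.finite(positions))) stop_invalid("positions must be finite")
  model <- match.arg(model, motion_model_names())
  structure(
    list(positions = positions, grid = grid, model = model,
         params = params, seed = seed),
    class = "spt_trajectory")
}

#' @export
print.spt_trajectory <- function(x, ...) {
  cat(sprintf("<spt_trajectory> %s, N = %d frames x K = %d (seed %s)\n",
              x$model, x$grid$n_frames, x$grid$k_interp,
              format(x$seed)))
  invisible(x)
}

#' Motion-model labels understood by the package
#' @return Character vector of the seven model names.
#' @export
motion_model_names <- function() {
  c("BM", "DBM", "ATTM", "CTRW", "FBM", "LW", "SBM")
}

# (N*K) x 3 matrix of positions in simulation order.
traj_flat <- function(traj) {
  p <- traj$positions
  d <- dim(p)
  m <- aperm(p, c(2, 1, 3))
  dim(m) <- c(d[1] * d[2], 3)
  m
}

flat_to_array <- function(flat, grid) {
  a <- array(flat, dim = c(grid$k_interp, grid$n_frames, 3))
  aperm(a, c(2, 1, 3))
}

# Per-frame summary position: the interpolation slot nearest the centre of
# the exposure window (coverage and per-frame reporting use this).
central_k <- function(grid) as.integer(ceiling(grid$k_interp / 2))

#' Per-frame summary positions
#'
#' Returns the N x 3 matrix of positions at each frame's central
#' interpolation time, the convention used for per-frame credible intervals
#' and coverage scoring.
#' @param traj An `spt_trajectory`.
#' @return N x 3 matrix (micrometres).
#' @export
frame_positions <- function(traj) {
  kc <- central_k(traj$grid)
  traj$positions[, kc, , drop = TRUE]
}
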