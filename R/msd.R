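#' Mean squared displacement of a trajectory ensemble
#'
#' Computes the MSD over an ensemble of trajectories sharing one time
#' grid, and fits the log-log slope (the empirical anomalous exponent) by
#' least squares. Two averaging conventions are available:
#' \describe{
#'   \item{`"ensemble"` (default)}{displacement from the trajectory origin,
#'     averaged over the ensemble only: `E|R(t) - R(0)|^2`. This is the
#'     quantity whose power law defines the anomalous exponent for aging,
#'     weakly non-ergodic models (CTRW, SBM, ATTM), whose time-averaged
#'     MSD scales differently.}
#'   \item{`"time"`}{squared displacement averaged over all start points
#'     of every trajectory and then over the ensemble (the conventional
#'     single-trajectory estimator).}
#' }
#' Lags are converted to seconds with the grid's mean step.
#'
#' @param trajs A single `spt_trajectory` or a list of them (same grid).
#' @param max_lag Largest lag (in grid steps) to evaluate; default one
#'   quarter of the series length for `"time"`, all lags for
#'   `"ensemble"`.
#' @param average `"ensemble"` or `"time"` (see above).
#' @param fit_lags Lags used in the slope fit (default: all computed
#'   lags).
#' @return A list with `table` (data.frame: lag_steps, lag_s, msd_um2) and
#'   `slope` (log-log fitted exponent; `NA` with a warning for degenerate,
#'   e.g. constant, ensembles).
#' @export
msd_curve <- function(trajs, max_lag = NULL,
                      average = c("ensemble", "time"), fit_lags = NULL) {
  if (inherits(trajs, "spt_trajectory")) trajs <- list(trajs)
  average <- match.arg(average)
  stopifnot(length(trajs) >= 1L,
            all(vapply(trajs, inherits, TRUE, "spt_trajectory")))
  grid <- trajs[[1]]$grid
  L <- grid$n_frames * grid$k_interp
  if (L < 2L) stop_invalid("MSD requires at least 2 time points")
  if (is.null(max_lag)) {
    max_lag <- if (average == "time") max(1L, L %/% 4L) else L - 1L
  }
  max_lag <- min(as.integer(max_lag), L - 1L)
  lags <- seq_len(max_lag)
  acc <- numeric(max_lag)
  cnt <- numeric(max_lag)
  for (tr in trajs) {
    p <- traj_flat(tr)
    if (average == "ensemble") {
      d <- p[lags + 1L, , drop = FALSE] -
        matrix(p[1, ], max_lag, 3, byrow = TRUE)
      acc <- acc + rowSums(d * d)
      cnt <- cnt + 1
    } else {
      for (lag in lags) {
        d <- p[(lag + 1):L, , drop = FALSE] - p[1:(L - lag), , drop = FALSE]
        acc[lag] <- acc[lag] + sum(d * d)
        cnt[lag] <- cnt[lag] + (L - lag)
      }
    }
  }
  msd <- acc / cnt
  tt <- grid_times(grid)
  dt <- (tt[L] - tt[1]) / (L - 1L)
  tab <- data.frame(lag_steps = lags, lag_s = lags * dt, msd_um2 = msd)
  if (is.null(fit_lags)) fit_lags <- lags
  fit_lags <- intersect(fit_lags, lags)
  ok <- msd[fit_lags] > 0
  slope <- NA_real_
  if (sum(ok) >= 2L) {
    slope <- unname(coef(lm(log(msd[fit_lags][ok]) ~
                              log(tab$lag_s[fit_lags][ok])))[2])
  } else {
    warning("MSD degenerate (constant ensemble?); slope undefined",
            call. = FALSE)
  }
  list(table = tab, slope = slope, average = average)
}
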