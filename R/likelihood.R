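#' Log-density of the initial-position prior
#'
#' Log of the trivariate Gaussian initial-localization density evaluated at
#' the first position: the optics-limited knowledge of where the particle
#' starts.
#'
#' @param R1 First position (3-vector, micrometres).
#' @param prior An [initial_position_prior()].
#' @return Log-density (signed so larger = more probable).
#' @export
log_initial <- function(R1, prior) {
  stopifnot(inherits(prior, "spt_initial_prior"))
  R1 <- check_R1(R1)
  sds <- c(prior$sigma_xy, prior$sigma_xy, prior$sigma_z)
  sum(dnorm(R1, prior$mu, sds, log = TRUE))
}

#' Pixel-wise Gamma emission log-likelihood
#'
#' Sum over all pixels and frames of the high-gain EMCCD Gamma log-density
#' of the measured ADU counts `w` given the expected signal `u`:
#' `-w / (2G/phi) + (beta*u/2 - 1) log w - (beta*u/2) log(2G/phi)
#'  - lgamma(beta*u/2)`. Counts at or below `w_floor` are clipped up to the
#' floor (the `log w` term diverges at 0 for shapes below 1); the number of
#' clipped pixels is returned as attribute `n_clipped`.
#'
#' @param w N x P matrix of ADU counts or an `spt_image_stack`.
#' @param u N x P matrix of expected signal or an `spt_expected_signal`.
#' @param camera A [camera_params()] record.
#' @param w_floor Clipping floor in ADU (default 1e-3).
#' @return Scalar log-likelihood with attribute `n_clipped`.
#' @export
log_emission <- function(w, u, camera, w_floor = 1e-3) {
  if (inherits(w, "spt_image_stack")) w <- w$w
  if (inherits(u, "spt_expected_signal")) u <- u$u
  if (!identical(dim(w), dim(u))) stop_invalid("w and u must share a shape")
  shape <- camera$quantum_efficiency * u / 2
  scl <- 2 * camera$gain / camera$conversion
  degen <- shape == 0
  if (any(degen & w != 0)) {
    stop_invalid("positive count observed on a pixel with zero expected signal")
  }
  w <- w[!degen]
  shape <- shape[!degen]
  n_clipped <- sum(w < w_floor)
  w <- pmax(w, w_floor)
  ll <- sum(-w / scl + (shape - 1) * log(w) - shape * log(scl) -
              lgamma(shape))
  structure(ll, n_clipped = n_clipped)
}

#' Brownian-motion log-likelihood of a trajectory
#'
#' Transition-density term of the decomposed log-likelihood: the sum over
#' all consecutive steps on the flattened (frame, interpolation) grid,
#' including the step across each frame boundary (whose lag spans the dead
#' time), of `-( |dR|^2 / (4 D dt) + (3/2) log(4 pi D dt) )`. Short lags at
#' small diffusivity make the per-step density exceed one, which is why
#' this term is typically positive at reference imaging conditions.
#'
#' @param traj An `spt_trajectory` with at least 2 time points.
#' @param D Diffusivity in um^2/s (> 0).
#' @return Scalar log-density.
#' @export
log_motion_bm <- function(traj, D) {
  stopifnot(inherits(traj, "spt_trajectory"))
  check_scalar(D, "D", lower = 0, open_lower = TRUE)
  pos <- traj_flat(traj)
  if (nrow(pos) < 2L) stop_invalid("motion term needs >= 2 time points")
  dts <- grid_dts(traj$grid)
  if (any(dts <= 0)) stop_invalid("non-positive lag in time grid")
  dr2 <- rowSums(diff(pos)^2)
  -sum(dr2 / (4 * D * dts) + 1.5 * log(4 * pi * D * dts))
}

#' Exact motion log-likelihood under alternative Gaussian motion models
#'
#' Evaluates the trajectory's exact Gaussian log-density under the named
#' model: DBM (independent Gaussian steps with drift mean `v * dt`), SBM
#' (independent steps with variance `2 * D_alpha * (s_l^alpha -
#' s_(l-1)^alpha)` in elapsed time), or FBM (full multivariate normal per
#' axis with covariance `D * (s^2H + t^2H - |s - t|^2H)` relative to the
#' first position; dense, limited to 512 time points).
#'
#' @param traj An `spt_trajectory`.
#' @param model One of `"DBM"`, `"SBM"`, `"FBM"`.
#' @param params Named list: DBM needs `D` and `v`; SBM needs `alpha` (and
#'   optional `convention`); FBM needs `hurst` and `D`.
#' @return Scalar log-density.
#' @export
log_motion_alt <- function(traj, model = c("DBM", "SBM", "FBM"),
                           params = list()) {
  stopifnot(inherits(traj, "spt_trajectory"))
  model <- match.arg(model)
  pos <- traj_flat(traj)
  L <- nrow(pos)
  if (L < 2L) stop_invalid("motion term needs >= 2 time points")
  tt <- grid_times(traj$grid)
  s <- tt - tt[1]
  if (model == "DBM") {
    D <- check_scalar(params$D %||% 1, "D", lower = 0, open_lower = TRUE)
    v <- params$v %||% c(0, 0, 0)
    dts <- diff(s)
    inc <- diff(pos) - outer(dts, as.numeric(v))
    sdv <- sqrt(2 * D * dts)
    return(sum(dnorm(inc, 0, matrix(sdv, L - 1L, 3L), log = TRUE)))
  }
  if (model == "SBM") {
    alpha <- check_scalar(params$alpha %||% 1, "alpha", lower = 0,
                          upper = 2, open_lower = TRUE)
    conv <- params$convention %||% "power_time"
    d_alpha <- params$d_alpha %||% (1 / (2 * gamma(1 + alpha)))
    vars <- if (conv == "power_time") 2 * d_alpha * diff(s^alpha)
            else 2 * d_alpha * diff(s)^alpha
    if (any(vars <= 0)) stop_invalid("degenerate SBM step variance")
    inc <- diff(pos)
    return(sum(dnorm(inc, 0, matrix(sqrt(vars), L - 1L, 3L), log = TRUE)))
  }
  # FBM: dense per-axis multivariate normal of positions relative to R1
  hurst <- check_scalar(params$hurst %||% 0.5, "hurst", lower = 0, upper = 1,
                        open_lower = TRUE, open_upper = TRUE)
  D <- check_scalar(params$D %||% 1, "D", lower = 0, open_lower = TRUE)
  if (L > 513L) stop_invalid("FBM dense likelihood limited to <= 512 steps")
  si <- s[-1]
  h2 <- 2 * hurst
  S <- D * (outer(si^h2, rep(1, L - 1L)) + outer(rep(1, L - 1L), si^h2) -
              abs(outer(si, si, `-`))^h2)
  ch <- tryCatch(chol(S), error = function(e) {
    stop_invalid("singular FBM covariance: %s", conditionMessage(e))
  })
  centered <- sweep(pos[-1, , drop = FALSE], 2, pos[1, ])
  z <- backsolve(ch, centered, transpose = TRUE)
  ld <- sum(log(diag(ch)))
  m <- L - 1L
  sum(-0.5 * colSums(z^2)) - 3 * ld - 3 * m / 2 * log(2 * pi)
}

#' Decomposed log-likelihood of an image stack at a trajectory
#'
#' The headline audit: evaluates the three additive terms of the
#' log-likelihood — initial-position (optics prior), pixel-wise Gamma
#' emission, and BM motion — and the emission-versus-motion contribution
#' fraction. The initial-position term is booked on the emission side
#' (it belongs to the optics/measurement description, not the transition
#' density).
#'
#' @param stack An `spt_image_stack`.
#' @param traj The trajectory at which to evaluate (ground truth or a
#'   posterior summary).
#' @param optics,camera,emission Parameter records used to build the
#'   expected signal.
#' @param prior Initial-position prior; defaults to the ROI centre with
#'   the optics' PSF widths.
#' @param D Motion-model diffusivity (um^2/s) for the BM term.
#' @param w_floor Clipping floor forwarded to [log_emission()].
#' @param fraction_method `"abs"` (default): emission fraction =
#'   |emission side| / (|emission side| + |motion|); `"magnitude"`: ratio
#'   of log10 magnitudes.
#' @return Object of class `spt_loglik_decomposition`: list with
#'   `ln_initial`, `ln_emission_pixels`, `ln_motion`, `ln_total`,
#'   `emission_fraction`, `n_clipped`.
#' @export
decompose <- function(stack, traj, optics = optics_params(),
                      camera = camera_params(),
                      emission = emission_params(), prior = NULL, D = 1,
                      w_floor = 1e-3,
                      fraction_method = c("abs", "magnitude")) {
  stopifnot(inherits(stack, "spt_image_stack"),
            inherits(traj, "spt_trajectory"))
  fraction_method <- match.arg(fraction_method)
  if (is.null(prior)) {
    ext <- roi_extent(camera)
    prior <- initial_position_prior(c(ext / 2, ext / 2, 0),
                                    optics$sigma_xy, optics$sigma_z)
  }
  u <- expected_signal(traj, optics, camera, emission)
  ln_init <- log_initial(traj_flat(traj)[1, ], prior)
  ln_emis <- log_emission(stack$w, u$u, camera, w_floor = w_floor)
  ln_mot <- log_motion_bm(traj, D)
  n_clipped <- attr(ln_emis, "n_clipped")
  ln_emis <- as.numeric(ln_emis)
  emis_side <- ln_init + ln_emis
  frac <- if (fraction_method == "abs") {
    abs(emis_side) / (abs(emis_side) + abs(ln_mot))
  } else {
    log10(abs(emis_side)) /
      (log10(abs(emis_side)) + log10(max(abs(ln_mot), 1)))
  }
  structure(
    list(ln_initial = ln_init, ln_emission_pixels = ln_emis,
         ln_motion = ln_mot, ln_total = ln_init + ln_emis + ln_mot,
         emission_fraction = frac, n_clipped = n_clipped,
         fraction_method = fraction_method, D = D),
    class = "spt_loglik_decomposition")
}

#' @export
print.spt_loglik_decomposition <- function(x, ...) {
  cat(sprintf(paste0(
    "<spt_loglik_decomposition>\n",
    "  ln P(R1)            : %12.2f\n",
    "  ln P(Data|Position) : %12.2f  (pixels; %d clipped)\n",
    "  ln P(Position|Motion): %11.2f\n",
    "  ln L                : %12.2f\n",
    "  emission fraction   : %12.4f\n"),
    x$ln_initial, x$ln_emission_pixels, x$n_clipped, x$ln_motion,
    x$ln_total, x$emission_fraction))
  invisible(x)
}
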