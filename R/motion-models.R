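#' Initial-position prior
#'
#' The particle's first localization is modelled as a trivariate Gaussian
#' centred on the optical axis `mu = (mu_x, mu_y, 0)` with lateral width
#' `sigma_xy` (PSF lateral width) and axial width `sigma_z` (PSF axial
#' width): the static localization uncertainty of a diffraction-limited
#' widefield microscope.
#'
#' @param mu Length-3 centre in micrometres; third component must be 0.
#' @param sigma_xy,sigma_z Positive widths in micrometres.
#' @return Object of class `spt_initial_prior`.
#' @export
initial_position_prior <- function(mu = c(0, 0, 0), sigma_xy = 0.1,
                                   sigma_z = 0.4) {
  if (length(mu) != 3L || !all(is.finite(mu))) {
    stop_invalid("'mu' must be a finite 3-vector")
  }
  if (mu[3] != 0) stop_invalid("axial component of 'mu' must be exactly 0")
  check_scalar(sigma_xy, "sigma_xy", lower = 0, open_lower = TRUE)
  check_scalar(sigma_z, "sigma_z", lower = 0, open_lower = TRUE)
  structure(list(mu = as.numeric(mu), sigma_xy = sigma_xy, sigma_z = sigma_z),
            class = "spt_initial_prior")
}

#' Draw an initial particle position
#'
#' Samples from N(mu, diag(sigma_xy^2, sigma_xy^2, sigma_z^2)).
#'
#' @param prior An [initial_position_prior()].
#' @param seed Integer RNG seed (`NULL` to use the current RNG state).
#' @return Length-3 position in micrometres.
#' @export
draw_initial_position <- function(prior, seed = NULL) {
  stopifnot(inherits(prior, "spt_initial_prior"))
  with_rng_seed(seed, {
    prior$mu + rnorm(3) * c(prior$sigma_xy, prior$sigma_xy, prior$sigma_z)
  })
}

# Shared driver: build a trajectory from per-step increment draws.
# `increments` is an (L-1) x 3 matrix; returns positions in flattened order.
positions_from_increments <- function(R1, increments, grid) {
  L <- grid$n_frames * grid$k_interp
  pos <- matrix(0, L, 3)
  pos[1, ] <- R1
  if (L > 1L) {
    pos[-1, ] <- rep(R1, each = L - 1L) + apply(increments, 2, cumsum)
  }
  pos
}

check_R1 <- function(R1) {
  if (length(R1) != 3L || !all(is.finite(R1))) {
    stop_invalid("'R1' must be a finite 3-vector (micrometres)")
  }
  as.numeric(R1)
}

# Core Brownian increments used by both BM and DBM so that DBM with v = 0
# reproduces BM bit-for-bit under the same seed.
bm_increments <- function(dts, D) {
  sdv <- sqrt(2 * D * dts)
  matrix(rnorm(3L * length(dts)), ncol = 3L) * sdv
}

#' Simulate Brownian motion (BM)
#'
#' Isotropic 3D random walk: successive positions differ by independent
#' Gaussian increments with per-axis variance `2 * D * dt` over each lag
#' `dt` of the time grid.
#'
#' @param R1 Initial position (3-vector, micrometres).
#' @param grid A [time_grid()].
#' @param D Diffusivity in um^2/s (> 0).
#' @param seed Integer RNG seed.
#' @return An `spt_trajectory`.
#' @export
simulate_bm <- function(R1, grid, D = 1, seed = NULL) {
  R1 <- check_R1(R1)
  check_scalar(D, "D", lower = 0, open_lower = TRUE)
  with_rng_seed(seed, {
    inc <- bm_increments(grid_dts(grid), D)
    trajectory(positions_from_increments(R1, inc, grid), grid, "BM",
               list(D = D), seed %||% NA_integer_)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate drifted Brownian motion (DBM)
#'
#' BM plus a deterministic flow `v * dt` per step. When `v` is `NULL` a
#' scalar drift speed is drawn uniformly on (0, 1] um/s (lower limit
#' enforced at machine precision) and applied along x + y only: drift is
#' restricted to the azimuthal (image) plane so the particle stays in focus.
#'
#' @inheritParams simulate_bm
#' @param v Drift velocity 3-vector in um/s, or `NULL` to draw one.
#' @export
simulate_dbm <- function(R1, grid, D = 1, v = NULL, seed = NULL) {
  R1 <- check_R1(R1)
  check_scalar(D, "D", lower = 0, open_lower = TRUE)
  with_rng_seed(seed, {
    if (is.null(v)) {
      speed <- max(runif(1), .Machine$double.eps)
      v <- c(speed, speed, 0)
    }
    if (length(v) != 3L || !all(is.finite(v))) {
      stop_invalid("'v' must be a finite 3-vector (um/s)")
    }
    dts <- grid_dts(grid)
    inc <- bm_increments(dts, D) + outer(dts, as.numeric(v))
    trajectory(positions_from_increments(R1, inc, grid), grid, "DBM",
               list(D = D, v = as.numeric(v)), seed %||% NA_integer_)
  })
}

# Inverse-CDF sampler for the truncated power-law diffusivity density
# P(D) propto D^(sigma_exp - 1) on [d_min, d_max].
draw_attm_diffusivity <- function(n, sigma_exp, d_min, d_max) {
  u <- runif(n)
  (d_min^sigma_exp + u * (d_max^sigma_exp - d_min^sigma_exp))^(1 / sigma_exp)
}

#' Simulate annealed transient time motion (ATTM)
#'
#' Piecewise Brownian motion: the walker repeatedly draws a local
#' diffusivity from the truncated power law P(D) propto D^(sigma_exp - 1)
#' on `[d_min, d_max]` and keeps it for a deterministic sojourn
#' `tau = D^(-gamma_exp) * time_unit` before redrawing. The effective
#' anomalous exponent is `alpha = sigma_exp / gamma_exp`. Patch changes
#' happen in continuous time; the Gaussian increment over each grid lag
#' uses the time-integral of the piecewise-constant diffusivity.
#'
#' @inheritParams simulate_bm
#' @param sigma_exp Power-law exponent (> 0) of the diffusivity density.
#' @param gamma_exp Sojourn exponent; must lie in
#'   (sigma_exp, sigma_exp + 1).
#' @param d_min,d_max Truncation bounds of the diffusivity support
#'   (um^2/s).
#' @param time_unit Seconds per sojourn unit; defaults to the grid frame
#'   period so sojourns are O(frames).
#' @export
simulate_attm <- function(R1, grid, sigma_exp = 0.8, gamma_exp = 1.0,
                          d_min = 1e-3, d_max = 1,
                          time_unit = grid$frame_period, seed = NULL) {
  R1 <- check_R1(R1)
  check_scalar(sigma_exp, "sigma_exp", lower = 0, open_lower = TRUE)
  check_scalar(gamma_exp, "gamma_exp", lower = sigma_exp,
               upper = sigma_exp + 1, open_lower = TRUE, open_upper = TRUE)
  check_scalar(d_min, "d_min", lower = 0, open_lower = TRUE)
  check_scalar(d_max, "d_max", lower = d_min)
  with_rng_seed(seed, {
    tt <- grid_times(grid)
    total <- tt[length(tt)] - tt[1]
    # lay down patches until they cover the observation window
    Ds <- numeric(0); taus <- numeric(0)
    covered <- 0
    while (covered <= total) {
      d <- draw_attm_diffusivity(16L, sigma_exp, d_min, d_max)
      s <- d^(-gamma_exp) * time_unit
      Ds <- c(Ds, d); taus <- c(taus, s)
      covered <- covered + sum(s)
    }
    starts <- cumsum(c(0, taus))           # patch start times from t1
    cumint <- cumsum(c(0, Ds * taus))      # integral of D up to patch edges
    int_at <- function(t) {
      j <- findInterval(t, starts)
      cumint[j] + Ds[j] * (t - starts[j])
    }
    iv <- diff(int_at(tt - tt[1]))         # integral of D over each grid lag
    inc <- matrix(rnorm(3L * length(iv)), ncol = 3L) * sqrt(2 * iv)
    used <- seq_len(findInterval(total, starts))
    trajectory(positions_from_increments(R1, inc, grid), grid, "ATTM",
               list(sigma_exp = sigma_exp, gamma_exp = gamma_exp,
                    d_min = d_min, d_max = d_max, time_unit = time_unit,
                    patches = data.frame(diffusivity = Ds[used],
                                         sojourn = taus[used])),
               seed %||% NA_integer_)
  })
}

#' Simulate a continuous-time random walk (CTRW)
#'
#' The walker is trapped for power-law waiting times with survival tail
#' exponent `alpha` (density propto tau^-(alpha + 1), Pareto with minimum
#' `tau_min`), then makes an instantaneous Gaussian jump with per-axis
#' variance `2 * D * tau0`. Positions are piecewise-constant between jumps
#' and are evaluated exactly at the grid times.
#'
#' @inheritParams simulate_bm
#' @param alpha Waiting-time tail exponent in (0, 1).
#' @param tau0 Jump-variance time scale in seconds (the mobility scale;
#'   the paper-style "arbitrary" constant).
#' @param tau_min Minimum waiting time (s); defaults to one interpolation
#'   interval of the grid.
#' @export
simulate_ctrw <- function(R1, grid, alpha = 0.5, D = 1,
                          tau0 = grid$frame_period,
                          tau_min = grid$exposure / grid$k_interp,
                          seed = NULL) {
  R1 <- check_R1(R1)
  check_scalar(alpha, "alpha", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(D, "D", lower = 0, open_lower = TRUE)
  check_scalar(tau0, "tau0", lower = 0, open_lower = TRUE)
  check_scalar(tau_min, "tau_min", lower = 0, open_lower = TRUE)
  with_rng_seed(seed, {
    tt <- grid_times(grid)
    total <- tt[length(tt)] - tt[1]
    waits <- numeric(0)
    while (sum(waits) <= total) {
      waits <- c(waits, draw_pareto(32L, alpha, tau_min))
    }
    event_times <- cumsum(waits)
    keep <- event_times <= total
    n_jump <- sum(keep)
    # cumulative position after each jump; row 1 = start (no jump yet)
    cum <- matrix(R1, 1L, 3L, byrow = TRUE)
    if (n_jump > 0L) {
      jumps <- matrix(rnorm(3L * n_jump), ncol = 3L) * sqrt(2 * D * tau0)
      cs <- apply(jumps, 2, cumsum)
      if (n_jump == 1L) cs <- matrix(cs, 1L, 3L)
      cum <- rbind(cum, sweep(cs, 2, R1, `+`))
    }
    idx <- findInterval(tt - tt[1], event_times[keep]) + 1L
    pos <- cum[idx, , drop = FALSE]
    trajectory(pos, grid, "CTRW",
               list(alpha = alpha, D = D, tau0 = tau0, tau_min = tau_min),
               seed %||% NA_integer_)
  })
}

# Pareto sampler: density propto tau^-(alpha+1) on [tau_min, Inf).
draw_pareto <- function(n, alpha, tau_min) {
  tau_min * runif(n)^(-1 / alpha)
}

# Fractional-Gaussian-noise autocovariance at integer lags (unit variance).
fgn_autocov <- function(lags, hurst) {
  h2 <- 2 * hurst
  (abs(lags + 1)^h2 - 2 * abs(lags)^h2 + abs(lags - 1)^h2) / 2
}

# Davies-Harte circulant-embedding sampler for unit-variance fGn of length
# n. Embeds circ(gamma_0..gamma_n..gamma_1) of size 2n, diagonalizes by
# FFT, scales complex white noise by eigenvalue square roots, and inverse
# transforms. Falls back to an exact Cholesky factorization (with a
# warning) if the embedding has a materially negative eigenvalue.
davies_harte_fgn <- function(n, hurst) {
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(rnorm(1))
  m <- n
  g <- fgn_autocov(0:m, hurst)
  circ <- c(g, g[m:2])                       # length 2m
  lam <- Re(fft(circ))
  tol <- -1e-8 * max(abs(lam))
  if (min(lam) < tol) {
    warning("Davies-Harte embedding not nonnegative definite; ",
            "falling back to exact Cholesky sampling", call. = FALSE)
    G <- outer(seq_len(n), seq_len(n),
               function(i, j) fgn_autocov(abs(i - j), hurst))
    return(drop(crossprod(chol(G), rnorm(n))))
  }
  lam <- pmax(lam, 0)
  M <- 2L * m
  w <- complex(length.out = M)
  z <- rnorm(2L * m)                         # fixed-length draw per axis
  w[1] <- sqrt(lam[1]) * z[1]
  w[m + 1] <- sqrt(lam[m + 1]) * z[2]
  j <- seq_len(m - 1L)
  a <- z[2L * j + 1]
  b <- z[2L * j + 2]
  w[1 + j] <- sqrt(lam[1 + j] / 2) * complex(real = a, imaginary = b)
  w[M + 1 - j] <- Conj(w[1 + j])
  x <- Re(fft(w)) / sqrt(M)
  x[seq_len(n)]
}

#' Simulate fractional Brownian motion (FBM)
#'
#' Per-axis increments are fractional Gaussian noise with Hurst index
#' `hurst`, generated by the Davies-Harte circulant-embedding algorithm on
#' a uniform lattice (circulant embedding requires stationary increments on
#' equal lags; the grid's small dead-time irregularity is ignored for path
#' generation and grid times serve as labels). Increments are scaled so the
#' per-axis step variance is `2 * D * dt^(2 * hurst)` with
#' `dt = (t_L - t_1) / (L - 1)`; the three axes are independent.
#'
#' @inheritParams simulate_bm
#' @param hurst Hurst index in (0, 1); `hurst = 0.5` reduces to BM.
#' @param D Generalized diffusivity in um^2 / s^(2 * hurst).
#' @export
simulate_fbm <- function(R1, grid, hurst = 0.5, D = 1, seed = NULL) {
  R1 <- check_R1(R1)
  check_scalar(hurst, "hurst", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(D, "D", lower = 0, open_lower = TRUE)
  with_rng_seed(seed, {
    tt <- grid_times(grid)
    L <- length(tt)
    dt <- if (L > 1L) (tt[L] - tt[1]) / (L - 1L) else 0
    scale <- sqrt(2 * D) * dt^hurst
    inc <- vapply(1:3, function(a) davies_harte_fgn(L - 1L, hurst) * scale,
                  numeric(max(L - 1L, 0L)))
    trajectory(positions_from_increments(R1, inc, grid), grid, "FBM",
               list(hurst = hurst, D = D), seed %||% NA_integer_)
  })
}

# Uniform directions on the unit sphere.
draw_directions <- function(n) {
  m <- matrix(rnorm(3L * n), ncol = 3L)
  m / sqrt(rowSums(m^2))
}

#' Simulate a Levy walk (LW)
#'
#' Flights of power-law duration (density propto tau^-(sigma_exp + 1)) at
#' constant speed along directions sampled isotropically from the unit
#' sphere; the position advances linearly within each flight and is
#' evaluated exactly at the grid times. For `sigma_exp` in (0, 1) motion is
#' ballistic (anomalous exponent 2); for `sigma_exp` in (1, 2) it is
#' superdiffusive with exponent `3 - sigma_exp`.
#'
#' @inheritParams simulate_bm
#' @param sigma_exp Flight-time tail exponent in (0, 2).
#' @param speed Flight speed in um/s (> 0).
#' @param tau_min Minimum flight duration (s); defaults to one
#'   interpolation interval.
#' @export
simulate_lw <- function(R1, grid, sigma_exp = 1.5, speed = 1,
                        tau_min = grid$exposure / grid$k_interp,
                        seed = NULL) {
  R1 <- check_R1(R1)
  check_scalar(sigma_exp, "sigma_exp", lower = 0, upper = 2,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(speed, "speed", lower = 0, open_lower = TRUE)
  check_scalar(tau_min, "tau_min", lower = 0, open_lower = TRUE)
  with_rng_seed(seed, {
    tt <- grid_times(grid)
    total <- tt[length(tt)] - tt[1]
    durs <- numeric(0); dirs <- matrix(0, 0, 3)
    while (sum(durs) <= total) {
      durs <- c(durs, draw_pareto(16L, sigma_exp, tau_min))
      dirs <- rbind(dirs, draw_directions(16L))
    }
    ends <- cumsum(durs)
    starts <- c(0, ends[-length(ends)])
    # anchor position at the start of each flight
    disp <- dirs * durs * speed
    anchors <- rbind(R1, sweep(apply(disp, 2, cumsum), 2, R1, `+`))
    s <- tt - tt[1]
    j <- findInterval(s, ends) + 1L          # flight index containing s
    pos <- anchors[j, , drop = FALSE] +
      dirs[j, , drop = FALSE] * (s - starts[j]) * speed
    trajectory(pos, grid, "LW",
               list(sigma_exp = sigma_exp, speed = speed, tau_min = tau_min),
               seed %||% NA_integer_)
  })
}

#' Simulate scaled Brownian motion (SBM)
#'
#' Independent Gaussian increments whose variance grows as a power of
#' time: per-axis increment variance `2 * D_alpha * (s_l^alpha -
#' s_(l-1)^alpha)` with `s` the elapsed time since the trajectory start and
#' `D_alpha = 1 / (2 * gamma(1 + alpha))`, so the ensemble MSD is exactly
#' `6 * D_alpha * t^alpha`. Set `convention = "power_lag"` for the literal
#' `(dt_l)^alpha` reading instead.
#'
#' @inheritParams simulate_bm
#' @param alpha Anomalous exponent in (0, 2]; `alpha = 1` is BM with
#'   D = 1/2.
#' @param convention `"power_time"` (default, exact t^alpha ensemble MSD)
#'   or `"power_lag"`.
#' @export
simulate_sbm <- function(R1, grid, alpha = 1,
                         convention = c("power_time", "power_lag"),
                         seed = NULL) {
  R1 <- check_R1(R1)
  check_scalar(alpha, "alpha", lower = 0, upper = 2, open_lower = TRUE)
  convention <- match.arg(convention)
  d_alpha <- 1 / (2 * gamma(1 + alpha))
  with_rng_seed(seed, {
    tt <- grid_times(grid)
    s <- tt - tt[1]
    vars <- if (convention == "power_time") {
      2 * d_alpha * diff(s^alpha)
    } else {
      2 * d_alpha * diff(s)^alpha
    }
    inc <- matrix(rnorm(3L * length(vars)), ncol = 3L) * sqrt(vars)
    trajectory(positions_from_increments(R1, inc, grid), grid, "SBM",
               list(alpha = alpha, d_alpha = d_alpha,
                    convention = convention),
               seed %||% NA_integer_)
  })
}

#' Simulate a trajectory by model name
#'
#' Dispatcher over the seven implemented motion models; `params` are passed
#' to the model's simulator.
#'
#' @param model One of [motion_model_names()].
#' @inheritParams simulate_bm
#' @param params Named list of model parameters.
#' @export
simulate_trajectory <- function(model, R1, grid, params = list(),
                                seed = NULL) {
  model <- match.arg(model, motion_model_names())
  f <- switch(model,
              BM = simulate_bm, DBM = simulate_dbm, ATTM = simulate_attm,
              CTRW = simulate_ctrw, FBM = simulate_fbm, LW = simulate_lw,
              SBM = simulate_sbm)
  do.call(f, c(list(R1 = R1, grid = grid), params, list(seed = seed)))
}

#' Centre (and if needed uniformly rescale) a trajectory into the ROI
#'
#' Persistent trajectories (Levy walks, superdiffusive SBM) can span far
#' more than the imaged region of interest; before rendering they are
#' translated so their centroid sits at the ROI centre and, if their
#' lateral span exceeds the ROI minus a margin, shrunk by a single uniform
#' scalar applied to all three axes.
#'
#' @param traj An `spt_trajectory`.
#' @param roi_extent Lateral ROI side length in micrometres.
#' @param margin Fraction of the extent kept clear on each side, in
#'   [0, 0.5).
#' @return The transformed `spt_trajectory` (scale factor recorded in
#'   `params$rescale`).
#' @export
center_and_rescale <- function(traj, roi_extent, margin = 0.1) {
  stopifnot(inherits(traj, "spt_trajectory"))
  check_scalar(roi_extent, "roi_extent", lower = 0, open_lower = TRUE)
  check_scalar(margin, "margin", lower = 0, upper = 0.5, open_upper = TRUE)
  pos <- traj_flat(traj)
  target <- roi_extent * (1 - 2 * margin)
  ctr <- colMeans(pos)
  span <- max(apply(pos[, 1:2, drop = FALSE], 2,
                    function(v) diff(range(v))))
  scale <- if (span > target && span > 0) target / span else 1
  out <- sweep(pos, 2, ctr) * scale
  out[, 1] <- out[, 1] + roi_extent / 2
  out[, 2] <- out[, 2] + roi_extent / 2
  res <- trajectory(out, traj$grid, traj$model,
                    c(traj$params, list(rescale = scale)), traj$seed)
  res
}
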