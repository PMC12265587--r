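#' Bayesian single-particle trajectory inference by MCMC
#'
#' Metropolis-within-Gibbs sampler over the full set of intraframe
#' positions under the decomposed log-likelihood with a BM motion model
#' (regardless of which model generated the data). Each sweep performs,
#' per frame, (i) a rigid Gaussian random-walk translation of the frame's
#' K positions, (ii) a Gaussian perturbation of one randomly chosen
#' intraframe position, and (iii) an independence refresh of the whole
#' frame from the exact Brownian-bridge conditional given the neighbouring
#' anchors (motion prior cancels; emission-only acceptance); a sweep ends
#' with Metropolis steps on log D (log-uniform prior on `[1e-3, 1e2]`
#' um^2/s) and, mirroring trackers that do not know the emission
#' parameters, on the log photon rate H and log background flux F
#' (log-uniform priors spanning `[1e2, 1e8]` and `[1e2, 1e7]`). Proposal
#' scales adapt toward a 20-40% acceptance rate during the first third of
#' the chain (warm-up); adaptation is frozen afterwards. Initialization is
#' the background-subtracted brightness-weighted centroid of each frame
#' with z = 0.
#'
#' @param stack An `spt_image_stack` containing a single emitter.
#' @param optics,camera,emission Parameter records (defaults: reference
#'   configuration). `emission` provides the starting values for the
#'   sampled photon rate and background flux.
#' @param k_interp Number of intraframe positions K to infer.
#' @param n_iter Chain length (>= 1000).
#' @param seed Integer RNG seed.
#' @param sample_D Sample the BM diffusivity jointly (default) or keep it
#'   fixed at `D_init`.
#' @param sample_emission Sample H and F jointly (default) or keep them
#'   fixed at the values in `emission`.
#' @param D_init Initial (or fixed) diffusivity in um^2/s.
#' @param prior Initial-position prior; defaults to ROI centre with the
#'   optics PSF widths.
#' @param w_floor ADU clipping floor (see [log_emission()]).
#' @return Object of class `spt_chain`: `samples` (S x L x 3 with
#'   L = N * K flattened positions), `logliks`, `sampled_D`, `sampled_H`,
#'   `sampled_F`, `acceptance_rates`, `grid`, `seed`, and a `diagnostics`
#'   list (flags low-information stacks whose peak signal barely exceeds
#'   the background noise).
#' @export
mcmc_track <- function(stack, optics = optics_params(),
                       camera = camera_params(),
                       emission = emission_params(), k_interp = 8L,
                       n_iter = 6000L, seed = NULL, sample_D = TRUE,
                       sample_emission = TRUE, D_init = 1, prior = NULL,
                       w_floor = 1e-3) {
  stopifnot(inherits(stack, "spt_image_stack"))
  n_iter <- as.integer(check_scalar(n_iter, "n_iter", lower = 1000))
  check_scalar(D_init, "D_init", lower = 0, open_lower = TRUE)
  N <- nrow(stack$w)
  K <- as.integer(k_interp)
  grid <- time_grid(N, K, camera$frame_period, camera$exposure)
  L <- N * K
  npix <- camera$pixels_per_side
  ds <- camera$pixel_size_um
  ext <- roi_extent(camera)
  if (is.null(prior)) {
    prior <- initial_position_prior(c(ext / 2, ext / 2, 0),
                                    optics$sigma_xy, optics$sigma_z)
  }
  beta <- camera$quantum_efficiency
  scl <- 2 * camera$gain / camera$conversion
  tau <- camera$exposure
  H <- emission$photon_rate
  Fg <- emission$background_flux
  sample_emission <- sample_emission && H > 0 && Fg > 0
  sxy <- optics$sigma_xy
  sz <- optics$sigma_z
  dts <- grid_dts(grid)
  tt <- grid_times(grid)

  w <- stack$w
  logw <- log(pmax(w, w_floor))

  # brightness-weighted centroid initialization (background-subtracted)
  px_x <- rep((seq_len(npix) - 0.5) * ds, times = npix)
  px_y <- rep((seq_len(npix) - 0.5) * ds, each = npix)
  init <- matrix(0, N, 3)
  peak_z <- numeric(N)
  for (n in seq_len(N)) {
    med <- median(w[n, ])
    madv <- max(stats::mad(w[n, ]), 1e-12)
    peak_z[n] <- (max(w[n, ]) - med) / madv
    excess <- pmax(w[n, ] - med, 0)
    if (sum(excess) > 0) {
      init[n, 1] <- sum(excess * px_x) / sum(excess)
      init[n, 2] <- sum(excess * px_y) / sum(excess)
    } else {
      init[n, 1:2] <- ext / 2
    }
  }
  # background-only frames have max z-scores ~3.5 over ~1e3 pixels
  low_info <- mean(peak_z) < 4.2

  # per-frame signal field per unit photon rate (u = F ds^2 tau + H * S)
  frame_S <- function(pos_n) {
    cpp_frame_u(pos_n[, 1], pos_n[, 2], pos_n[, 3], npix, ds, sxy, sz,
                1.0, tau, 0.0)
  }

  with_rng_seed(seed, {
    pos <- matrix(0, L, 3)
    for (n in seq_len(N)) {
      rows <- ((n - 1L) * K + 1L):(n * K)
      pos[rows, ] <- matrix(init[n, ], K, 3, byrow = TRUE)
    }
    D <- D_init
    lnD_lim <- log(c(1e-3, 1e2))
    lnH_lim <- log(c(1e2, 1e8))
    lnF_lim <- log(c(1e2, 1e7))

    S <- matrix(0, npix * npix, N)
    emis_ll <- numeric(N)
    bgu <- Fg * ds^2 * tau
    for (n in seq_len(N)) {
      rows <- ((n - 1L) * K + 1L):(n * K)
      S[, n] <- frame_S(pos[rows, , drop = FALSE])
      emis_ll[n] <- cpp_gamma_loglik(w[n, ], logw[n, ], bgu + H * S[, n],
                                     beta, scl)
    }
    step_ll <- function(a, b, dt, Dv) {
      -(sum((b - a)^2) / (4 * Dv * dt) + 1.5 * log(4 * pi * Dv * dt))
    }
    motion_total <- function(Dv) {
      dr2 <- rowSums((pos[-1, , drop = FALSE] -
                        pos[-L, , drop = FALSE])^2)
      -sum(dr2 / (4 * Dv * dts) + 1.5 * log(4 * pi * Dv * dts))
    }
    mot <- motion_total(D)
    init_ll <- log_initial(pos[1, ], prior)

    scale_rigid <- rep(0.5 * ds, N)
    scale_one <- rep(0.5 * ds, N)
    # the axial posterior is ~sigma_z/sigma_xy times wider than the
    # lateral one; proposals keep that anisotropy so z mixes as fast
    axis_mult <- c(1, 1, sz / sxy)
    acc <- c(rigid = 0, single = 0, bridge = 0, D = 0, emission = 0)
    tries <- c(rigid = 0, single = 0, bridge = 0, D = 0, emission = 0)
    win_acc_r <- numeric(N); win_try_r <- numeric(N)
    win_acc_s <- numeric(N); win_try_s <- numeric(N)
    warmup <- n_iter %/% 3L

    samples <- array(NA_real_, dim = c(n_iter, L, 3))
    logliks <- numeric(n_iter)
    sampled_D <- numeric(n_iter)
    sampled_H <- numeric(n_iter)
    sampled_F <- numeric(n_iter)

    for (it in seq_len(n_iter)) {
      for (n in seq_len(N)) {
        rows <- ((n - 1L) * K + 1L):(n * K)
        # --- rigid frame translation -----------------------------------
        delta <- rnorm(3) * scale_rigid[n] * axis_mult
        newp <- pos[rows, , drop = FALSE] +
          matrix(delta, K, 3, byrow = TRUE)
        S_new <- frame_S(newp)
        ell_new <- cpp_gamma_loglik(w[n, ], logw[n, ], bgu + H * S_new,
                                    beta, scl)
        d_mot <- 0
        if (n > 1L) {
          l0 <- rows[1]
          d_mot <- d_mot +
            step_ll(pos[l0 - 1L, ], newp[1, ], dts[l0 - 1L], D) -
            step_ll(pos[l0 - 1L, ], pos[l0, ], dts[l0 - 1L], D)
        }
        if (n < N) {
          l1 <- rows[K]
          d_mot <- d_mot + step_ll(newp[K, ], pos[l1 + 1L, ], dts[l1], D) -
            step_ll(pos[l1, ], pos[l1 + 1L, ], dts[l1], D)
        }
        d_init <- if (n == 1L) log_initial(newp[1, ], prior) - init_ll else 0
        lr <- (ell_new - emis_ll[n]) + d_mot + d_init
        tries["rigid"] <- tries["rigid"] + 1; win_try_r[n] <- win_try_r[n] + 1
        if (log(runif(1)) < lr) {
          pos[rows, ] <- newp
          S[, n] <- S_new
          emis_ll[n] <- ell_new
          mot <- mot + d_mot
          if (n == 1L) init_ll <- init_ll + d_init
          acc["rigid"] <- acc["rigid"] + 1; win_acc_r[n] <- win_acc_r[n] + 1
        }
        # --- single intraframe position --------------------------------
        kk <- if (K > 1L) sample.int(K, 1L) else 1L
        l <- rows[kk]
        newp <- pos[rows, , drop = FALSE]
        newp[kk, ] <- newp[kk, ] + rnorm(3) * scale_one[n] * axis_mult
        S_new <- frame_S(newp)
        ell_new <- cpp_gamma_loglik(w[n, ], logw[n, ], bgu + H * S_new,
                                    beta, scl)
        d_mot <- 0
        if (l > 1L) {
          d_mot <- d_mot +
            step_ll(pos[l - 1L, ], newp[kk, ], dts[l - 1L], D) -
            step_ll(pos[l - 1L, ], pos[l, ], dts[l - 1L], D)
        }
        if (l < L) {
          d_mot <- d_mot + step_ll(newp[kk, ], pos[l + 1L, ], dts[l], D) -
            step_ll(pos[l, ], pos[l + 1L, ], dts[l], D)
        }
        d_init <- if (l == 1L) log_initial(newp[1, ], prior) - init_ll else 0
        lr <- (ell_new - emis_ll[n]) + d_mot + d_init
        tries["single"] <- tries["single"] + 1; win_try_s[n] <- win_try_s[n] + 1
        if (log(runif(1)) < lr) {
          pos[rows, ] <- newp
          S[, n] <- S_new
          emis_ll[n] <- ell_new
          mot <- mot + d_mot
          if (l == 1L) init_ll <- init_ll + d_init
          acc["single"] <- acc["single"] + 1; win_acc_s[n] <- win_acc_s[n] + 1
        }
        # --- Brownian-bridge refresh of the whole frame ----------------
        # Independence proposal from the exact BM conditional given the
        # neighbouring anchors; the motion-prior factor cancels against
        # the proposal density, leaving an emission-only (plus, for the
        # first frame, initial-prior) acceptance ratio.
        if (N > 1L) {
          newp <- matrix(0, K, 3)
          if (n == N) {                       # free forward propagation
            prev <- pos[rows[1] - 1L, ]; prev_t <- tt[rows[1] - 1L]
            for (k2 in seq_len(K)) {
              tk <- tt[rows[k2]]
              newp[k2, ] <- prev + rnorm(3) * sqrt(2 * D * (tk - prev_t))
              prev <- newp[k2, ]; prev_t <- tk
            }
          } else if (n == 1L) {               # free backward propagation
            prev <- pos[rows[K] + 1L, ]; prev_t <- tt[rows[K] + 1L]
            for (k2 in rev(seq_len(K))) {
              tk <- tt[rows[k2]]
              newp[k2, ] <- prev + rnorm(3) * sqrt(2 * D * (prev_t - tk))
              prev <- newp[k2, ]; prev_t <- tk
            }
          } else {                            # bridge between anchors
            b <- pos[rows[K] + 1L, ]; tb <- tt[rows[K] + 1L]
            prev <- pos[rows[1] - 1L, ]; prev_t <- tt[rows[1] - 1L]
            for (k2 in seq_len(K)) {
              tk <- tt[rows[k2]]
              wgt <- (tk - prev_t) / (tb - prev_t)
              vv <- 2 * D * (tk - prev_t) * (tb - tk) / (tb - prev_t)
              newp[k2, ] <- prev + wgt * (b - prev) + rnorm(3) * sqrt(vv)
              prev <- newp[k2, ]; prev_t <- tk
            }
          }
          S_new <- frame_S(newp)
          ell_new <- cpp_gamma_loglik(w[n, ], logw[n, ], bgu + H * S_new,
                                      beta, scl)
          d_init <- if (n == 1L) log_initial(newp[1, ], prior) - init_ll else 0
          tries["bridge"] <- tries["bridge"] + 1
          if (log(runif(1)) < (ell_new - emis_ll[n]) + d_init) {
            pos[rows, ] <- newp
            S[, n] <- S_new
            emis_ll[n] <- ell_new
            if (n == 1L) init_ll <- init_ll + d_init
            mot <- motion_total(D)
            acc["bridge"] <- acc["bridge"] + 1
          }
        }
      }
      # --- diffusivity -------------------------------------------------
      if (sample_D) {
        lnD_new <- log(D) + rnorm(1) * 0.15
        tries["D"] <- tries["D"] + 1
        if (lnD_new >= lnD_lim[1] && lnD_new <= lnD_lim[2]) {
          mot_new <- motion_total(exp(lnD_new))
          if (log(runif(1)) < mot_new - mot) {
            D <- exp(lnD_new)
            mot <- mot_new
            acc["D"] <- acc["D"] + 1
          }
        }
      }
      # --- emission nuisance parameters (photon rate, background) -----
      if (sample_emission) {
        for (par in c("H", "F")) {
          tries["emission"] <- tries["emission"] + 1
          if (par == "H") {
            lnew <- log(H) + rnorm(1) * 0.05
            if (lnew < lnH_lim[1] || lnew > lnH_lim[2]) next
            H_try <- exp(lnew); bgu_try <- bgu
          } else {
            lnew <- log(Fg) + rnorm(1) * 0.02
            if (lnew < lnF_lim[1] || lnew > lnF_lim[2]) next
            H_try <- H; bgu_try <- exp(lnew) * ds^2 * tau
          }
          ell_try <- vapply(seq_len(N), function(n) {
            cpp_gamma_loglik(w[n, ], logw[n, ], bgu_try + H_try * S[, n],
                             beta, scl)
          }, numeric(1))
          if (log(runif(1)) < sum(ell_try) - sum(emis_ll)) {
            emis_ll <- ell_try
            if (par == "H") H <- H_try else {
              Fg <- exp(lnew); bgu <- bgu_try
            }
            acc["emission"] <- acc["emission"] + 1
          }
        }
      }
      # --- warm-up adaptation -----------------------------------------
      if (it <= warmup && it %% 25L == 0L) {
        rate_r <- ifelse(win_try_r > 0, win_acc_r / win_try_r, 0.3)
        rate_s <- ifelse(win_try_s > 0, win_acc_s / win_try_s, 0.3)
        scale_rigid <- scale_rigid * exp(pmin(pmax(rate_r - 0.3, -0.6), 0.6))
        scale_one <- scale_one * exp(pmin(pmax(rate_s - 0.3, -0.6), 0.6))
        win_acc_r[] <- 0; win_try_r[] <- 0
        win_acc_s[] <- 0; win_try_s[] <- 0
      }
      samples[it, , ] <- pos
      logliks[it] <- init_ll + sum(emis_ll) + mot
      sampled_D[it] <- D
      sampled_H[it] <- H
      sampled_F[it] <- Fg
    }
    structure(
      list(samples = samples, logliks = logliks, sampled_D = sampled_D,
           sampled_H = sampled_H, sampled_F = sampled_F,
           acceptance_rates = as.list(ifelse(tries > 0, acc / tries, NA)),
           grid = grid, seed = seed %||% NA_integer_, sample_D = sample_D,
           sample_emission = sample_emission,
           diagnostics = list(low_position_information = low_info,
                              mean_peak_z = mean(peak_z),
                              scale_rigid = scale_rigid,
                              scale_single = scale_one)),
      class = "spt_chain")
  })
}

#' @export
print.spt_chain <- function(x, ...) {
  cat(sprintf(
    "<spt_chain> %d samples, N = %d frames x K = %d; acc rigid %.2f / single %.2f%s\n",
    length(x$logliks), x$grid$n_frames, x$grid$k_interp,
    x$acceptance_rates$rigid, x$acceptance_rates$single,
    if (x$sample_D) sprintf(" / D %.2f", x$acceptance_rates$D) else ""))
  invisible(x)
}

#' Remove MCMC burn-in
#'
#' Retains the stated (1-based, inclusive) iteration window of a chain;
#' the conventional windows are `[2e3, 6e3]` or `[3e3, 6e3]` on a 6e3
#' chain.
#'
#' @param chain An `spt_chain`.
#' @param burn_range Length-2 integer vector `c(first, last)` of samples to
#'   keep.
#' @return The windowed `spt_chain`.
#' @export
remove_burn_in <- function(chain, burn_range) {
  stopifnot(inherits(chain, "spt_chain"), length(burn_range) == 2L)
  S <- length(chain$logliks)
  lo <- as.integer(burn_range[1]); hi <- as.integer(burn_range[2])
  if (lo < 1L || hi > S || lo > hi) {
    stop_invalid("burn_range [%d, %d] outside chain length %d", lo, hi, S)
  }
  keep <- lo:hi
  chain$samples <- chain$samples[keep, , , drop = FALSE]
  chain$logliks <- chain$logliks[keep]
  chain$sampled_D <- chain$sampled_D[keep]
  if (!is.null(chain$sampled_H)) chain$sampled_H <- chain$sampled_H[keep]
  if (!is.null(chain$sampled_F)) chain$sampled_F <- chain$sampled_F[keep]
  chain
}

#' Per-frame credible bands
#'
#' Equal-tailed percentile intervals, per frame and axis, of the chain's
#' per-frame summary position (the central interpolation slot).
#'
#' @param chain A (post-burn-in) `spt_chain` with at least 100 samples.
#' @param level Credible level in (0, 1]; `level = 1` gives the min/max
#'   envelope.
#' @return Object of class `spt_credible_bands`: list with N x 3 matrices
#'   `lower` and `upper` and the `level`.
#' @export
credible_bands <- function(chain, level = 0.98) {
  stopifnot(inherits(chain, "spt_chain"))
  check_scalar(level, "level", lower = 0, upper = 1, open_lower = TRUE)
  S <- length(chain$logliks)
  if (S < 100L) stop_invalid("need >= 100 post-burn-in samples, have %d", S)
  grid <- chain$grid
  kc <- central_k(grid)
  idx <- ((seq_len(grid$n_frames) - 1L) * grid$k_interp) + kc
  a <- (1 - level) / 2
  lower <- upper <- matrix(0, grid$n_frames, 3,
                           dimnames = list(NULL, c("x", "y", "z")))
  for (j in 1:3) {
    sub <- chain$samples[, idx, j, drop = FALSE]
    lower[, j] <- apply(sub, 2, quantile, probs = a, names = FALSE)
    upper[, j] <- apply(sub, 2, quantile, probs = 1 - a, names = FALSE)
  }
  structure(list(lower = lower, upper = upper, level = level),
            class = "spt_credible_bands")
}

#' Credible-interval coverage of ground truth
#'
#' Fraction of frames whose true position lies inside the credible band on
#' every listed axis; the in-frame image-plane criterion uses
#' `axes = c("x", "y")`.
#'
#' @param bands An [credible_bands()] result.
#' @param truth The ground-truth `spt_trajectory` (same frame count).
#' @param axes Axes that must all be covered.
#' @return Scalar fraction in [0, 1], with attribute `n_covered` and
#'   `n_frames`.
#' @export
coverage_fraction <- function(bands, truth, axes = c("x", "y")) {
  stopifnot(inherits(bands, "spt_credible_bands"),
            inherits(truth, "spt_trajectory"))
  axes <- match.arg(axes, c("x", "y", "z"), several.ok = TRUE)
  tp <- frame_positions(truth)
  if (is.null(dim(tp))) tp <- matrix(tp, 1, 3)
  if (nrow(tp) != nrow(bands$lower)) {
    stop_invalid("frame count mismatch: truth %d vs bands %d", nrow(tp),
                 nrow(bands$lower))
  }
  j <- match(axes, c("x", "y", "z"))
  inside <- tp[, j, drop = FALSE] >= bands$lower[, j, drop = FALSE] &
    tp[, j, drop = FALSE] <= bands$upper[, j, drop = FALSE]
  cov <- rowSums(inside) == length(j)
  structure(mean(cov), n_covered = sum(cov), n_frames = length(cov))
}
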